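#' Annealed mutation schedule
#'
#' The maximum mutation size decreases over generations (simulated
#' annealing):
#' \deqn{\mu(T) = \frac{\mu_0 - \mu_\infty}{1 + (T/\psi)^3} + \mu_\infty}
#' so that \eqn{\mu(0) = \mu_0}, \eqn{\mu(\psi) = (\mu_0 - \mu_\infty)/2 +
#' \mu_\infty}, and \eqn{\mu(T) \to \mu_\infty} as \eqn{T \to \infty}. Early
#' generations explore trait space rapidly; later generations refine.
#'
#' The standard regime has `mu0 > mu_inf > 0`; degenerate schedules
#' (`mu0 = mu_inf`, or zero) are permitted for controlled experiments with
#' mutation switched off.
#'
#' @param mu0 initial maximum mutation size.
#' @param mu_inf asymptotic maximum mutation size.
#' @param psi time constant (generations) at which half the decay from
#'   `mu0` toward `mu_inf` has occurred.
#' @return An object of class `mutation_schedule`.
#' @export
mutation_schedule <- function(mu0 = 0.1, mu_inf = 0.001, psi = 50) {
  if (mu0 < mu_inf || mu_inf < 0) stop("require mu0 >= mu_inf >= 0", call. = FALSE)
  if (psi <= 0) stop("psi must be positive", call. = FALSE)
  structure(list(mu0 = mu0, mu_inf = mu_inf, psi = psi),
            class = "mutation_schedule")
}

#' Maximum mutation size at generation T
#'
#' @param T generation (non-negative; vectorized).
#' @param schedule a [mutation_schedule()].
#' @return `mu(T)`, monotone non-increasing in `T`.
#' @export
mutation_scale <- function(T, schedule) {
  if (any(T < 0)) stop("T must be non-negative", call. = FALSE)
  (schedule$mu0 - schedule$mu_inf) / (1 + (T / schedule$psi)^3) +
    schedule$mu_inf
}

#' Perturb a value by a uniform mutation
#'
#' Adds an independent draw from `Uniform[-mu, mu]` to each element. No
#' clamping is applied: traits can evolve outside `[0, 1]`, and negative
#' evolved values do occur.
#'
#' @param x numeric vector of trait or allele values.
#' @param mu maximum perturbation size, `>= 0`.
#' @return perturbed values.
#' @export
mutate_value <- function(x, mu) {
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (mu == 0) return(x)
  x + stats::runif(length(x), -mu, mu)
}

.TRAITS <- c("alpha", "delta", "rho")

#' Create a founding population
#'
#' Every trait of every founder is drawn independently from `Uniform[0, 1]`.
#' In diploid mode both alleles of each trait are independent draws, and
#' each founding allele copy receives a unique lineage tag (per trait) so
#' that later genotype tabulation does not depend on numeric rounding of
#' evolved allele values.
#'
#' @param n population size.
#' @param mode `"clonal"`, `"averaging"` (phenotype-averaging sexual) or
#'   `"diploid"` (codominant random mating).
#' @return An object of class `population`: list with `mode`, `phenotype`
#'   (`n x 3` matrix, columns `alpha`, `delta`, `rho`), and for diploid mode
#'   `alleles` and `tags` (`n x 3 x 2` arrays).
#' @export
init_population <- function(n, mode = c("clonal", "averaging", "diploid")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (mode == "clonal" && n %% 2L != 0L)
    stop("clonal mode requires an even population size", call. = FALSE)
  if (mode != "clonal" && n %% 4L != 0L)
    stop("sexual modes require a population size divisible by 4", call. = FALSE)
  if (mode == "diploid") {
    alleles <- array(stats::runif(n * 3L * 2L), dim = c(n, 3L, 2L),
                     dimnames = list(NULL, .TRAITS, NULL))
    tags <- array(seq_len(2L * n), dim = c(n, 3L, 2L))
    # unique tags within each trait: copy 1 gets 1..n, copy 2 gets n+1..2n
    for (tr in 1:3) {
      tags[, tr, 1L] <- seq_len(n)
      tags[, tr, 2L] <- n + seq_len(n)
    }
    new_population(mode, .diploid_phenotype(alleles), alleles, tags)
  } else {
    ph <- matrix(stats::runif(n * 3L), n, 3L, dimnames = list(NULL, .TRAITS))
    new_population(mode, ph)
  }
}

new_population <- function(mode, phenotype, alleles = NULL, tags = NULL) {
  structure(list(mode = mode, phenotype = phenotype,
                 alleles = alleles, tags = tags),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d agents, %s mode\n", nrow(x$phenotype), x$mode))
  invisible(x)
}

#' Population size
#' @param pop a `population`.
#' @return integer number of agents.
#' @export
pop_size <- function(pop) nrow(pop$phenotype)

# codominance: each trait expressed as the mean of its two allele values
.diploid_phenotype <- function(alleles) {
  ph <- (alleles[, , 1L, drop = FALSE] + alleles[, , 2L, drop = FALSE]) / 2
  matrix(ph, nrow = dim(alleles)[1L], ncol = 3L,
         dimnames = list(NULL, .TRAITS))
}

#' Hard selection of the fittest half
#'
#' Agents are ranked by final biomass (the fitness measure) and the top
#' half is retained regardless of absolute fitness. Ties are broken by a
#' stable sort on agent index.
#'
#' @param pop a `population`.
#' @param fitness numeric vector of final biomasses, one per agent; must be
#'   finite (a non-finite fitness signals an engine bug).
#' @return the parent `population` of size `pop_size(pop)/2`.
#' @export
select_fittest <- function(pop, fitness) {
  n <- pop_size(pop)
  if (n == 0L) stop("empty population", call. = FALSE)
  if (length(fitness) != n) stop("one fitness per agent required", call. = FALSE)
  if (any(!is.finite(fitness)))
    stop("non-finite fitness: upstream engine bug", call. = FALSE)
  keep <- order(-fitness, seq_len(n))[seq_len(n %/% 2L)]
  subset_population(pop, keep)
}

subset_population <- function(pop, idx) {
  new_population(pop$mode,
                 pop$phenotype[idx, , drop = FALSE],
                 if (!is.null(pop$alleles)) pop$alleles[idx, , , drop = FALSE],
                 if (!is.null(pop$tags)) pop$tags[idx, , , drop = FALSE])
}

#' Clonal reproduction
#'
#' The parents pass into the next generation unchanged; each parent also
#' contributes one clone whose three trait values are independently
#' perturbed by `Uniform[-mu(T), mu(T)]`.
#'
#' @param parents parent `population` (the selected fittest half).
#' @param T current generation (sets the mutation scale).
#' @param schedule a [mutation_schedule()].
#' @return next-generation `population` of size `2 * pop_size(parents)`.
#' @export
reproduce_clonal <- function(parents, T, schedule) {
  if (parents$mode == "diploid")
    stop("clonal reproduction expects a haploid-phenotype population",
         call. = FALSE)
  mu <- mutation_scale(T, schedule)
  np <- pop_size(parents)
  clones <- matrix(mutate_value(as.numeric(parents$phenotype), mu), np, 3L,
                   dimnames = list(NULL, .TRAITS))
  new_population(parents$mode, rbind(parents$phenotype, clones))
}

#' Phenotype-averaging sexual reproduction
#'
#' Parents are shuffled and paired at random; each pair produces four
#' progeny whose trait values are the means of the parents' values, each
#' then independently mutated. The next generation consists of progeny only
#' (full replacement).
#'
#' @inheritParams reproduce_clonal
#' @return next-generation `population` of size `2 * pop_size(parents)`.
#' @export
reproduce_averaging <- function(parents, T, schedule) {
  np <- pop_size(parents)
  if (np %% 2L != 0L) stop("need an even number of parents", call. = FALSE)
  mu <- mutation_scale(T, schedule)
  perm <- sample.int(np)
  p1 <- parents$phenotype[perm[seq(1L, np, by = 2L)], , drop = FALSE]
  p2 <- parents$phenotype[perm[seq(2L, np, by = 2L)], , drop = FALSE]
  mid <- (p1 + p2) / 2
  progeny <- mid[rep(seq_len(np %/% 2L), each = 4L), , drop = FALSE]
  progeny <- matrix(mutate_value(as.numeric(progeny), mu), 2L * np, 3L,
                    dimnames = list(NULL, .TRAITS))
  new_population(parents$mode, progeny)
}

#' Diploid codominant random mating
#'
#' Parents are shuffled and paired at random (hermaphroditic: no sexes,
#' every parent in exactly one pair). Each pair produces four progeny. For
#' each progeny and each trait independently, one allele is drawn uniformly
#' from each parent's two alleles (random segregation, no linkage between
#' traits); every inherited allele value is then mutated with `mu(T)` while
#' its lineage tag is inherited unchanged. The expressed phenotype of each
#' trait is the mean of its two allele values (codominance). Full
#' replacement.
#'
#' @inheritParams reproduce_clonal
#' @return next-generation `population` of size `2 * pop_size(parents)`.
#' @export
reproduce_diploid <- function(parents, T, schedule) {
  if (parents$mode != "diploid" || is.null(parents$alleles))
    stop("diploid reproduction requires diploid genotypes", call. = FALSE)
  np <- pop_size(parents)
  if (np %% 2L != 0L) stop("need an even number of parents", call. = FALSE)
  mu <- mutation_scale(T, schedule)
  perm <- sample.int(np)
  i1 <- perm[seq(1L, np, by = 2L)]
  i2 <- perm[seq(2L, np, by = 2L)]
  n_out <- 2L * np
  # progeny row p descends from pair (p - 1) %/% 4 + 1
  par1 <- i1[rep(seq_along(i1), each = 4L)]
  par2 <- i2[rep(seq_along(i2), each = 4L)]
  alleles <- array(NA_real_, dim = c(n_out, 3L, 2L),
                   dimnames = list(NULL, .TRAITS, NULL))
  tags <- array(NA_integer_, dim = c(n_out, 3L, 2L))
  for (tr in 1:3) {
    pick1 <- 1L + (stats::runif(n_out) < 0.5)  # which of parent 1's copies
    pick2 <- 1L + (stats::runif(n_out) < 0.5)
    a1 <- parents$alleles[cbind(par1, tr, pick1)]
    a2 <- parents$alleles[cbind(par2, tr, pick2)]
    alleles[, tr, 1L] <- mutate_value(a1, mu)
    alleles[, tr, 2L] <- mutate_value(a2, mu)
    tags[, tr, 1L] <- parents$tags[cbind(par1, tr, pick1)]
    tags[, tr, 2L] <- parents$tags[cbind(par2, tr, pick2)]
  }
  new_population("diploid", .diploid_phenotype(alleles), alleles, tags)
}

.reproduce <- function(parents, T, schedule) {
  switch(parents$mode,
         clonal = reproduce_clonal(parents, T, schedule),
         averaging = reproduce_averaging(parents, T, schedule),
         diploid = reproduce_diploid(parents, T, schedule))
}

#' Configuration for an evolutionary epoch
#'
#' Bundles the full study configuration. Defaults are the baseline: a
#' 20 x 20 toroidal grid (400 patches), 100 ticks per generation, 200
#' generations, baseline resource/foraging parameters and mutation
#' schedule, initial biomass 0.
#'
#' @param n_agents population size (even for clonal mode, divisible by 4
#'   for the sexual modes).
#' @param mode reproduction mode: `"clonal"`, `"averaging"` or `"diploid"`.
#' @param n_ticks ticks per generation.
#' @param generations generations per epoch (`G`).
#' @param grid a [grid_spec()].
#' @param r_params a [resource_params()].
#' @param f_params a [foraging_params()].
#' @param schedule a [mutation_schedule()].
#' @param B0 initial biomass of every agent at the start of each generation.
#' @param self_excluded see [sense_environment()].
#' @param snapshot_at generations at which full phenotype/fitness snapshots
#'   are kept.
#' @param engine tick engine, `"compiled"` or `"reference"`.
#' @return An object of class `epoch_config`.
#' @export
epoch_config <- function(n_agents, mode = c("clonal", "averaging", "diploid"),
                         n_ticks = 100L, generations = 200L,
                         grid = grid_spec(), r_params = resource_params(),
                         f_params = foraging_params(),
                         schedule = mutation_schedule(), B0 = 0,
                         self_excluded = TRUE,
                         snapshot_at = integer(0),
                         engine = c("compiled", "reference")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  n_agents <- as.integer(n_agents)
  generations <- as.integer(generations)
  if (generations < 1L) stop("need at least one generation", call. = FALSE)
  if (mode == "clonal" && n_agents %% 2L != 0L)
    stop("clonal mode requires even n_agents", call. = FALSE)
  if (mode != "clonal" && n_agents %% 4L != 0L)
    stop("sexual modes require n_agents divisible by 4", call. = FALSE)
  structure(list(n_agents = n_agents, mode = mode,
                 n_ticks = as.integer(n_ticks), generations = generations,
                 grid = grid, r_params = r_params, f_params = f_params,
                 schedule = schedule, B0 = B0,
                 self_excluded = isTRUE(self_excluded),
                 snapshot_at = as.integer(snapshot_at), engine = engine),
            class = "epoch_config")
}

#' Run an evolutionary epoch
#'
#' Initializes a founding population at generation `T = 1` and for each
#' `T = 1..G`: draws random agent placements, initializes a fresh resource
#' landscape, resets biomasses to `B0`, runs one generation of the foraging
#' engine, selects the fittest half, and (for `T < G`) produces the next
#' generation with mutation scale `mu(T)`. A single RNG stream drives the
#' whole run in documented order (placement, resources, tick decisions,
#' reproduction), so a fixed seed reproduces the trajectory bit-exactly.
#'
#' @param config an [epoch_config()].
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   first.
#' @return An object of class `epoch_result`: list with `config`, `seed`,
#'   `generations` (data.frame of per-generation summaries, one row per
#'   `T`), `snapshots` (named list of phenotype/fitness matrices at the
#'   requested generations), and `final` (the evaluated final-generation
#'   `population` with its `fitness`).
#' @export
run_epoch <- function(config, seed = NULL) {
  if (!inherits(config, "epoch_config")) stop("need an epoch_config", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  G <- config$generations
  pop <- init_population(config$n_agents, config$mode)
  nbins <- n_cells(config$grid)
  recs <- vector("list", G)
  snaps <- list()
  final <- NULL
  for (T in seq_len(G)) {
    agents <- new_agents(pop$phenotype, grid = config$grid, biomass = config$B0)
    landscape <- init_resources(config$grid, config$r_params)
    gen <- run_generation(agents, landscape, config$f_params, config$r_params,
                          n = config$n_ticks,
                          self_excluded = config$self_excluded,
                          engine = config$engine)
    recs[[T]] <- cbind(generation = T, gen$record)
    if (T %in% config$snapshot_at)
      snaps[[as.character(T)]] <- list(phenotype = pop$phenotype,
                                       fitness = gen$fitness)
    if (T == G) {
      final <- list(population = pop, fitness = gen$fitness)
    } else {
      parents <- select_fittest(pop, gen$fitness)
      pop <- .reproduce(parents, T, config$schedule)
    }
  }
  structure(list(config = config, seed = seed,
                 generations = do.call(rbind, recs),
                 snapshots = snaps, final = final),
            class = "epoch_result")
}

#' @export
print.epoch_result <- function(x, ...) {
  g <- x$generations
  cat(sprintf(
    "<epoch_result> %d agents (%s), %d generations; final mean fitness %.3g\n",
    x$config$n_agents, x$config$mode, x$config$generations,
    g$mean_fitness[nrow(g)]))
  invisible(x)
}

#' Agent density of a configuration
#'
#' @param n_agents number of agents.
#' @param grid a [grid_spec()].
#' @return agents per patch (e.g. 10 agents on the default 400-cell grid
#'   give 0.025).
#' @export
agent_density <- function(n_agents, grid = grid_spec()) {
  n_agents / n_cells(grid)
}

#' Write an epoch result to disk
#'
#' Writes `generations` as CSV and a JSON summary (config echo, seed,
#' per-generation records) if \pkg{jsonlite} is available.
#'
#' @param x an `epoch_result`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_epoch_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "generations.csv")
  utils::write.csv(x$generations, csv, row.names = FALSE)
  paths <- csv
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    js <- file.path(dir, "epoch.json")
    cfg <- x$config
    cfg$grid <- unclass(cfg$grid)
    jsonlite::write_json(
      list(config = lapply(unclass(cfg), unclass), seed = x$seed,
           generations = x$generations),
      js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}
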