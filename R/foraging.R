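#' Foraging and biomass parameters
#'
#' Parameters of within-patch resource extraction and agent energetics.
#' An agent staying in cell `k` alongside `N - 1` other stayers extracts
#' \deqn{F = \min\{R/N,\; uR/(h + R + qN)\}}
#' per capita, converting it to biomass at rate `kappa`. An agent that
#' relocates (including "in place") extracts nothing and is charged fraction
#' `c` of its biomass. Defaults are the baseline configuration.
#'
#' @param u maximum extraction rate (resource units per tick).
#' @param h half-saturation efficiency (resource units).
#' @param q intraspecific competition coefficient.
#' @param kappa biomass conversion rate, in `[0, 1]`.
#' @param c cost of moving, a fraction of biomass in `[0, 1)`.
#' @return An object of class `foraging_params`.
#' @export
foraging_params <- function(u = 10, h = 20, q = 0.5, kappa = 0.1, c = 0.1) {
  if (u < 0 || h < 0 || q < 0) stop("require u, h, q >= 0", call. = FALSE)
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]", call. = FALSE)
  if (c < 0 || c >= 1) stop("c must be in [0, 1)", call. = FALSE)
  structure(list(u = u, h = h, q = q, kappa = kappa, c = c),
            class = "foraging_params")
}

#' Create a cohort of agents
#'
#' @param phenotype numeric matrix (or data.frame) with columns `alpha`,
#'   `delta`, `rho`, one row per agent.
#' @param location integer cell indices; if `NULL`, agents are placed
#'   uniformly at random over the grid (independent draws; multiple agents
#'   per cell allowed).
#' @param grid a [grid_spec()] (needed when `location` is `NULL`).
#' @param biomass initial biomass, recycled; default 0.
#' @return data.frame with columns `id`, `location`, `biomass`, `alpha`,
#'   `delta`, `rho`.
#' @export
new_agents <- function(phenotype, location = NULL, grid = NULL, biomass = 0) {
  phenotype <- as.matrix(phenotype)
  n <- nrow(phenotype)
  if (is.null(location)) {
    if (is.null(grid)) stop("supply `grid` for random placement", call. = FALSE)
    location <- floor(stats::runif(n) * n_cells(grid)) + 1L
  }
  data.frame(id = seq_len(n),
             location = as.integer(location),
             biomass = rep_len(biomass, n),
             alpha = phenotype[, "alpha"],
             delta = phenotype[, "delta"],
             rho = phenotype[, "rho"],
             row.names = NULL)
}

#' Per-capita extraction rate in a cell
#'
#' `min(R/N, u R / (h + R + q N))`: extraction saturates in the resource
#' stock, is depressed by crowding through `q`, and can never exceed an
#' equal share of the stock, so total extraction `N * F` never exceeds `R`.
#'
#' @param R resource stock (vectorized).
#' @param N number of extracting agents in the cell, `>= 1`.
#' @param params a [foraging_params()].
#' @return per-capita extraction `F`.
#' @export
extraction_rate <- function(R, N, params) {
  if (any(N < 1)) stop("extraction_rate requires N >= 1", call. = FALSE)
  if (any(R < 0)) stop("negative resource stock", call. = FALSE)
  pmin(R / N, params$u * R / (params$h + R + params$q * N))
}

#' Advance the intragenerational clock by one tick (reference engine)
#'
#' One synchronous update: (1) every agent decides stay/relocate from the
#' same time-`t` landscape state; (2) relocating agents change cell
#' ("move in place" keeps the cell); (3) in each cell the staying agents
#' extract at the common per-capita rate and gain `kappa * F` biomass;
#' (4) every relocating agent is charged fraction `c` of its biomass and
#' extracts nothing; (5) each cell's resource renews from its
#' post-extraction stock; (6) occupancy is recomputed from the new
#' locations. Agents that moved in place do not join the extracting set but
#' do count in the next tick's occupancy.
#'
#' This is the plain-R reference implementation; [run_generation()] uses a
#' compiled engine by default and this function as its correctness oracle.
#'
#' @param agents data.frame as from [new_agents()].
#' @param landscape a `landscape` with `J` consistent with `agents$location`.
#' @param f_params a [foraging_params()].
#' @param r_params a [resource_params()] (regrowth step).
#' @param self_excluded passed to [sense_environment()].
#' @return list with updated `agents`, `landscape`, and `stats` (per-cell
#'   extractor counts `N_k`, per-capita extraction `F_k`, post-extraction
#'   stock `R_star`, plus per-agent `stayed` flags).
#' @export
step_tick <- function(agents, landscape, f_params, r_params,
                      self_excluded = TRUE) {
  n <- nrow(agents)
  nc <- n_cells(landscape$grid)
  stayed <- logical(n)
  new_loc <- integer(n)
  for (i in seq_len(n)) {
    env <- sense_environment(agents$location[i], landscape, self_excluded)
    d <- decide_move(env, movement_params(agents$alpha[i], agents$delta[i],
                                          agents$rho[i]))
    stayed[i] <- d$kind == "STAY"
    new_loc[i] <- d$cell
  }
  N_k <- tabulate(new_loc[stayed], nbins = nc)
  F_k <- numeric(nc)
  occ <- which(N_k > 0L)
  if (length(occ))
    F_k[occ] <- extraction_rate(landscape$R[occ], N_k[occ], f_params)
  biomass <- agents$biomass
  biomass[stayed] <- biomass[stayed] + f_params$kappa * F_k[new_loc[stayed]]
  biomass[!stayed] <- (1 - f_params$c) * biomass[!stayed]
  # F <= R/N guarantees N*F <= R mathematically; clamp the rounding residue
  R_star <- pmax(landscape$R - N_k * F_k, 0)
  landscape$R <- regrow(R_star, r_params)
  agents$biomass <- biomass
  agents$location <- new_loc
  landscape$J <- tabulate(new_loc, nbins = nc)
  list(agents = agents, landscape = landscape,
       stats = list(N_k = N_k, F_k = F_k, R_star = R_star, stayed = stayed))
}

#' Run one generation of the intragenerational clock
#'
#' Applies [step_tick()] `n` times (default 100 ticks per generation) and
#' returns the final agent states. The final biomass `B(n)` is the fitness
#' measure used by the evolutionary layer.
#'
#' Two engines are available: `"compiled"` (the default, an Rcpp
#' implementation of the same update) and `"reference"` (the plain-R
#' [step_tick()] loop). Both consume the same RNG stream in the same order
#' (one uniform draw per argmax tie), so a fixed seed reproduces the same
#' trajectory on either engine.
#'
#' @param agents data.frame as from [new_agents()].
#' @param landscape a freshly initialized `landscape`; its `J` is recomputed
#'   from `agents$location` before the first tick.
#' @param f_params a [foraging_params()].
#' @param r_params a [resource_params()].
#' @param n number of ticks (length of the intragenerational cycle).
#' @param self_excluded whether an agent's own-cell occupancy excludes
#'   itself in perception (default `TRUE`).
#' @param engine `"compiled"` or `"reference"`.
#' @return list with final `agents`, final `landscape`, `fitness` (the final
#'   biomass vector) and `record` (one-row data.frame of generation
#'   summaries: total biomass, mean/sd fitness, mean fitness of the top
#'   half, mean/sd of each trait).
#' @export
run_generation <- function(agents, landscape, f_params, r_params,
                           n = 100L, self_excluded = TRUE,
                           engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer", call. = FALSE)
  landscape$J <- tabulate(agents$location, nbins = n_cells(landscape$grid))
  if (engine == "compiled") {
    nbr <- neighbor_index_matrix(landscape$grid)
    nnbr <- rowSums(!is.na(nbr))
    nbr[is.na(nbr)] <- 0L
    out <- run_generation_cpp(
      loc = agents$location - 1L, biomass = agents$biomass,
      alpha = agents$alpha, delta = agents$delta, rho = agents$rho,
      R = landscape$R, nbr = nbr - 1L, nnbr = as.integer(nnbr),
      n_ticks = n, u = f_params$u, h = f_params$h, q = f_params$q,
      kappa = f_params$kappa, cost = f_params$c,
      r = r_params$r, s = r_params$s, g = r_params$g,
      self_excluded = self_excluded)
    agents$location <- out$location + 1L
    agents$biomass <- out$biomass
    landscape$R <- out$R
    landscape$J <- tabulate(agents$location, nbins = n_cells(landscape$grid))
  } else {
    for (t in seq_len(n)) {
      st <- step_tick(agents, landscape, f_params, r_params, self_excluded)
      agents <- st$agents
      landscape <- st$landscape
    }
  }
  fit <- agents$biomass
  top <- fit[order(-fit, agents$id)][seq_len(max(1L, nrow(agents) %/% 2L))]
  record <- data.frame(
    total_biomass = sum(fit),
    mean_fitness = mean(fit), sd_fitness = stats::sd(fit),
    mean_fitness_top = mean(top),
    mean_alpha = mean(agents$alpha), sd_alpha = stats::sd(agents$alpha),
    mean_delta = mean(agents$delta), sd_delta = stats::sd(agents$delta),
    mean_rho = mean(agents$rho), sd_rho = stats::sd(agents$rho))
  list(agents = agents, landscape = landscape, fitness = fit, record = record)
}
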