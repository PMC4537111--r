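#' Total biomass produced by a generation
#'
#' The fitness measure summed across all agents: `sum_a B_a(n)`.
#'
#' @param fitness numeric vector of final biomasses, or an `epoch_result`
#'   (in which case the per-generation totals are returned).
#' @return scalar total, or the per-generation total-biomass vector for an
#'   `epoch_result`.
#' @export
total_biomass_per_generation <- function(fitness) {
  if (inherits(fitness, "epoch_result"))
    return(fitness$generations$total_biomass)
  sum(fitness)
}

#' Configuration for a replicate-run comparison experiment
#'
#' Describes the study design: one [epoch_config()] template, how many
#' replicate epochs to run per reproduction mode, which modes to compare,
#' and the phase boundaries over which per-run biomass totals are
#' aggregated (default an initial 125-generation burn-in phase and a
#' subsequent 125-generation approach-to-equilibrium phase).
#'
#' Run `r` of every mode uses seed `base_seed + r - 1`, recorded in the
#' output, so any single run is re-runnable in isolation.
#'
#' @param base an [epoch_config()]; its `mode` field is overridden by
#'   `modes`.
#' @param n_runs replicate epochs per mode.
#' @param modes character vector of reproduction modes to compare.
#' @param base_seed integer seed base.
#' @param phases list of `c(first, last)` generation ranges; must be
#'   disjoint, ordered and within `1..generations`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(base, n_runs = 10L,
                              modes = c("clonal", "diploid"),
                              base_seed = 1L,
                              phases = list(c(1L, 125L), c(126L, 250L))) {
  stopifnot(inherits(base, "epoch_config"))
  last_end <- 0L
  for (ph in phases) {
    if (length(ph) != 2L || ph[1L] > ph[2L] || ph[1L] <= last_end ||
        ph[2L] > base$generations)
      stop("phases must be disjoint, ordered ranges within 1..G", call. = FALSE)
    last_end <- ph[2L]
  }
  structure(list(base = base, n_runs = as.integer(n_runs), modes = modes,
                 base_seed = as.integer(base_seed), phases = phases),
            class = "experiment_config")
}

#' Run a multi-replicate comparison experiment
#'
#' Runs `n_runs` independent epochs per reproduction mode with distinct
#' recorded seeds, tracks the total biomass produced each generation, and
#' aggregates per-run totals over the configured phases.
#'
#' @param config an [experiment_config()].
#' @param verbose print one progress line per completed run.
#' @return An object of class `experiment_result`: list with `runs`
#'   (data.frame: `mode`, `run`, `seed`, one `phase<i>_total` column per
#'   phase, `epoch_total`), `trajectories` (data.frame: `mode`, `run`,
#'   `generation`, `total_biomass`), and `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  runs <- list()
  trajs <- list()
  for (mode in config$modes) {
    cfg <- config$base
    cfg$mode <- mode
    if (mode == "clonal" && cfg$n_agents %% 2L != 0L)
      stop("clonal mode requires even n_agents", call. = FALSE)
    if (mode != "clonal" && cfg$n_agents %% 4L != 0L)
      stop("sexual modes require n_agents divisible by 4", call. = FALSE)
    for (r in seq_len(config$n_runs)) {
      seed <- config$base_seed + r - 1L
      ep <- run_epoch(cfg, seed = seed)
      tot <- ep$generations$total_biomass
      row <- data.frame(mode = mode, run = r, seed = seed)
      for (i in seq_along(config$phases)) {
        ph <- config$phases[[i]]
        row[[paste0("phase", i, "_total")]] <- sum(tot[ph[1L]:ph[2L]])
      }
      row$epoch_total <- sum(tot)
      runs[[length(runs) + 1L]] <- row
      trajs[[length(trajs) + 1L]] <-
        data.frame(mode = mode, run = r,
                   generation = ep$generations$generation,
                   total_biomass = tot)
      if (verbose)
        message(sprintf("mode=%s run=%d seed=%d epoch_total=%.0f",
                        mode, r, seed, row$epoch_total))
    }
  }
  structure(list(runs = do.call(rbind, runs),
                 trajectories = do.call(rbind, trajs),
                 config = config),
            class = "experiment_result")
}

#' Compare two reproduction modes on per-run phase totals
#'
#' Welch's two-sided t-test for a difference in mean phase totals between
#' the two modes, and an F-ratio test for unequal variances, computed on
#' the per-run totals of the requested phase.
#'
#' @param result an `experiment_result` with at least two runs per mode.
#' @param phase phase index (1-based).
#' @param modes the two modes to compare; defaults to the first two in the
#'   experiment.
#' @return list of class `mode_comparison`: per-mode `n`, `mean` and `var`
#'   of the phase totals, Welch `t`, `df` and `p_value`, and the variance
#'   ratio `F` with its `p_value_var`.
#' @export
compare_modes <- function(result, phase = 1L, modes = NULL) {
  if (is.null(modes)) modes <- result$config$modes[1:2]
  col <- paste0("phase", phase, "_total")
  if (!col %in% names(result$runs)) stop("no such phase", call. = FALSE)
  x <- result$runs[[col]][result$runs$mode == modes[1L]]
  y <- result$runs[[col]][result$runs$mode == modes[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two runs per mode", call. = FALSE)
  tt <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  vt <- stats::var.test(x, y)
  structure(list(modes = modes, phase = phase,
                 n = c(length(x), length(y)),
                 mean = c(mean(x), mean(y)),
                 var = c(stats::var(x), stats::var(y)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 F = unname(vt$statistic), p_value_var = vt$p.value),
            class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf("<mode_comparison> phase %d: %s vs %s\n", x$phase,
              x$modes[1L], x$modes[2L]))
  cat(sprintf("  means %.1f vs %.1f | Welch t = %.3f (df %.1f), p = %.3g\n",
              x$mean[1L], x$mean[2L], x$t, x$df, x$p_value))
  cat(sprintf("  vars  %.1f vs %.1f | F = %.3f, p = %.3g\n",
              x$var[1L], x$var[2L], x$F, x$p_value_var))
  invisible(x)
}
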