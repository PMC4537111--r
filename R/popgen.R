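#' Classify evolved phenotypes into morphs
#'
#' Groups agents into discrete movement types ("morphs") by single-linkage
#' agglomerative clustering in the 3-D trait space (alpha, delta, rho), cut
#' at a fixed gap threshold: two agents belong to the same morph if they
#' are connected by a chain of neighbors closer than the threshold. The
#' default threshold 0.03 is on the scale of late-epoch mutation noise, so
#' within-morph mutational scatter does not split morphs.
#'
#' @param phenotypes matrix or data.frame with columns `alpha`, `delta`,
#'   `rho`, one row per agent.
#' @param gap_threshold linkage distance above which clusters are separate
#'   morphs.
#' @param fitness optional fitness vector, summarized per morph.
#' @return An object of class `morph_table`: data.frame with one row per
#'   morph (`morph`, `n`, mean and sd of each trait and of fitness if
#'   given), sorted by mean `alpha`; the per-agent morph assignment is
#'   attached as attribute `"membership"`.
#' @export
classify_morphs <- function(phenotypes, gap_threshold = 0.03, fitness = NULL) {
  ph <- as.matrix(phenotypes)[, .TRAITS, drop = FALSE]
  n <- nrow(ph)
  if (n == 0L) stop("empty phenotype list", call. = FALSE)
  if (n == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(ph), method = "single")
    cl <- stats::cutree(hc, h = gap_threshold)
  }
  groups <- split(seq_len(n), cl)
  tab <- do.call(rbind, lapply(groups, function(idx) {
    row <- data.frame(n = length(idx))
    for (tr in .TRAITS) {
      row[[paste0("mean_", tr)]] <- mean(ph[idx, tr])
      row[[paste0("sd_", tr)]] <- if (length(idx) > 1L) stats::sd(ph[idx, tr]) else 0
    }
    if (!is.null(fitness)) {
      row$mean_fitness <- mean(fitness[idx])
      row$sd_fitness <- if (length(idx) > 1L) stats::sd(fitness[idx]) else 0
    }
    row
  }))
  ord <- order(tab$mean_alpha)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(morph = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  # relabel membership to match the sorted table
  relabel <- match(seq_along(groups), ord)
  structure(tab, membership = relabel[cl], class = c("morph_table", "data.frame"))
}

#' Allele frequencies from genotype counts
#'
#' Each allele's frequency is its share of the `2N` allele copies:
#' `(2 n_ii + sum_j n_ij) / (2N)`.
#'
#' @param genotype_counts named non-negative counts of unordered diploid
#'   genotypes; names of the form `"a/b"` (allele labels separated by `/`,
#'   order irrelevant), e.g. `c("a1/a1" = 22, "a1/a2" = 38)`.
#' @return named numeric vector of allele frequencies (sums to 1).
#' @export
allele_frequencies <- function(genotype_counts) {
  parsed <- .parse_genotype_counts(genotype_counts)
  copies <- tapply(c(parsed$counts, parsed$counts),
                   c(parsed$a1, parsed$a2), sum)
  freqs <- stats::setNames(as.numeric(copies) / sum(copies), names(copies))
  freqs[order(names(freqs))]
}

.parse_genotype_counts <- function(genotype_counts) {
  if (is.null(names(genotype_counts)) || any(!nzchar(names(genotype_counts))))
    stop("genotype counts must be named 'allele1/allele2'", call. = FALSE)
  if (any(genotype_counts < 0)) stop("negative genotype count", call. = FALSE)
  if (sum(genotype_counts) <= 0) stop("all genotype counts are zero", call. = FALSE)
  parts <- strsplit(names(genotype_counts), "/", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("genotype names must contain exactly one '/'", call. = FALSE)
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  # canonicalize unordered genotypes and merge duplicates
  key <- ifelse(a1 <= a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
  counts <- tapply(as.numeric(genotype_counts), key, sum)
  parts <- strsplit(names(counts), "/", fixed = TRUE)
  list(a1 = vapply(parts, `[`, "", 1L),
       a2 = vapply(parts, `[`, "", 2L),
       counts = as.numeric(counts), key = names(counts))
}

#' Hardy-Weinberg expected genotype counts and goodness of fit
#'
#' From observed genotype counts at one locus, estimates allele frequencies
#' and computes the genotype counts expected under Hardy-Weinberg
#' equilibrium (`N p_i^2` for homozygotes, `2 N p_i p_j` for
#' heterozygotes), together with a chi-square goodness-of-fit statistic
#' over all genotype classes of the observed alleles with
#' `df = #classes - #alleles` (the allele frequencies being estimated from
#' the same data). Classes with zero expected count are excluded from the
#' statistic.
#'
#' @inheritParams allele_frequencies
#' @return An object of class `hw_result`: list with `alleles`,
#'   `frequencies`, `observed` and `expected` (named by genotype, all
#'   classes over the observed alleles), `n` (sample size), `chisq`, `df`
#'   and `p_value`.
#' @export
hw_expected_counts <- function(genotype_counts) {
  parsed <- .parse_genotype_counts(genotype_counts)
  freqs <- allele_frequencies(genotype_counts)
  alleles <- names(freqs)
  N <- sum(parsed$counts)
  # all unordered genotype classes over the observed alleles
  combos <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
  key <- paste(alleles[combos[, 1L]], alleles[combos[, 2L]], sep = "/")
  p1 <- freqs[combos[, 1L]]
  p2 <- freqs[combos[, 2L]]
  expected <- ifelse(combos[, 1L] == combos[, 2L],
                     N * p1^2, 2 * N * p1 * p2)
  names(expected) <- key
  observed <- stats::setNames(numeric(length(key)), key)
  observed[parsed$key] <- parsed$counts
  use <- expected > 0
  chisq <- sum((observed[use] - expected[use])^2 / expected[use])
  df <- sum(use) - length(alleles)
  structure(list(alleles = alleles, frequencies = freqs,
                 observed = observed, expected = expected, n = N,
                 chisq = chisq, df = df,
                 p_value = if (df > 0) stats::pchisq(chisq, df,
                                                    lower.tail = FALSE)
                           else NA_real_),
            class = "hw_result")
}

#' @export
print.hw_result <- function(x, ...) {
  cat(sprintf("<hw_result> N = %d, %d alleles\n", round(x$n),
              length(x$alleles)))
  print(data.frame(observed = x$observed, expected = round(x$expected, 1)))
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Tabulate genotype counts at one trait of a diploid population
#'
#' Counts unordered genotypes either by the lineage tags carried by each
#' allele copy (`by = "tag"`, exact, independent of numeric value) or by
#' binning allele values that lie within `tol` of each other (`by =
#' "value"`, for value-only snapshots where lineage is unknown; bins are
#' formed by single-linkage gaps larger than `tol` and labeled by their
#' mean value).
#'
#' @param pop a diploid `population`.
#' @param trait `"alpha"`, `"delta"` or `"rho"`.
#' @param by `"tag"` or `"value"`.
#' @param tol value-binning tolerance (only for `by = "value"`).
#' @return named numeric vector of genotype counts, usable by
#'   [allele_frequencies()] and [hw_expected_counts()].
#' @export
genotype_counts <- function(pop, trait = c("alpha", "delta", "rho"),
                            by = c("tag", "value"), tol = 0.02) {
  trait <- match.arg(trait)
  by <- match.arg(by)
  if (pop$mode != "diploid" || is.null(pop$alleles))
    stop("genotype tabulation requires a diploid population", call. = FALSE)
  tr <- match(trait, .TRAITS)
  if (by == "tag") {
    l1 <- as.character(pop$tags[, tr, 1L])
    l2 <- as.character(pop$tags[, tr, 2L])
  } else {
    vals <- c(pop$alleles[, tr, 1L], pop$alleles[, tr, 2L])
    bins <- bin_alleles(vals, tol)
    n <- pop_size(pop)
    l1 <- bins[seq_len(n)]
    l2 <- bins[n + seq_len(n)]
  }
  key <- ifelse(l1 <= l2, paste(l1, l2, sep = "/"), paste(l2, l1, sep = "/"))
  c(table(key))
}

#' Bin allele values by proximity
#'
#' One-dimensional single-linkage grouping: sorted values are split
#' wherever consecutive values differ by more than `tol`; each bin is
#' labeled by its rounded mean.
#'
#' @param values numeric allele values.
#' @param tol gap tolerance.
#' @return character vector of bin labels, aligned with `values`.
#' @export
bin_alleles <- function(values, tol = 0.02) {
  ord <- order(values)
  sorted <- values[ord]
  grp <- cumsum(c(1, diff(sorted) > tol))
  lab <- vapply(split(sorted, grp), function(v) sprintf("%.3f", mean(v)), "")
  out <- character(length(values))
  out[ord] <- lab[grp]
  out
}

#' Per-generation mean and SD of an expressed trait
#'
#' @param epoch an `epoch_result`.
#' @param trait `"alpha"`, `"delta"` or `"rho"`.
#' @return data.frame with columns `generation`, `mean`, `sd`.
#' @export
summarize_parameter_trajectory <- function(epoch,
                                           trait = c("alpha", "delta", "rho")) {
  trait <- match.arg(trait)
  g <- epoch$generations
  data.frame(generation = g$generation,
             mean = g[[paste0("mean_", trait)]],
             sd = g[[paste0("sd_", trait)]])
}
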