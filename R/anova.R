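# One-way ANOVA F statistic with a permutation p-value for group-wise
# phenotype comparisons (e.g. survival rate or chlorophyll content across
# haplotype or population groups).

#' Compare a phenotype across groups (one-way F + permutation p)
#'
#' The F statistic is computed from the classic sums-of-squares
#' decomposition, F = (SSB/(k-1)) / (SSW/(N-k)).  Because group sizes in
#' haplotype panels are small and unbalanced, the p-value is obtained by
#' label permutation rather than from the F distribution:
#' p = (1 + #\{F_perm >= F\}) / (n_perm + 1).  Under a fixed seed the result
#' is fully deterministic.
#'
#' @param x either a numeric vector of measurements, or a phenotype
#'   data.frame with an `accession` column (e.g. from [read_phenotypes()]).
#' @param grouping for a numeric `x`: a parallel vector of group labels; for
#'   a data.frame `x`: a named vector mapping accession to label (such as the
#'   haplotype column of a [classify_haplotypes()] result).
#' @param measure column of `x` to compare when `x` is a data.frame.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional integer seed for the permutations.
#' @return object of class `group_comparison`: list with `table` (per-group
#'   n/mean/sd), `statistic` (F), `p.value`, `df`, `n_perm`, `seed`.
#' @export
compare_groups <- function(x, grouping, measure = NULL, n_perm = 10000,
                           seed = NULL) {
  if (is.data.frame(x)) {
    if (is.null(measure) || !measure %in% names(x))
      stop2("`measure` must name a column of the phenotype table")
    if (is.null(names(grouping)))
      stop2("`grouping` must be named by accession when `x` is a data.frame")
    acc <- intersect(x$accession, names(grouping))
    if (!length(acc)) stop2("no accessions shared between phenotypes and grouping")
    values <- x[[measure]][match(acc, x$accession)]
    labels <- as.character(grouping[acc])
  } else {
    values <- as.numeric(x)
    labels <- as.character(grouping)
    if (length(values) != length(labels))
      stop2("`x` and `grouping` must have the same length")
  }
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  f <- factor(labels)
  k <- nlevels(f); N <- length(values)
  if (k < 2) stop2("need at least 2 groups")
  ng <- tabulate(f)
  if (any(ng < 2)) stop2("every group needs at least 2 observations")

  gsum <- rowsum(values, f)[, 1]
  gmean <- gsum / ng
  grand <- sum(values) / N
  ssb <- sum(ng * (gmean - grand)^2)
  sst <- sum((values - grand)^2)
  ssw <- sst - ssb
  if (ssw <= 0 && ssb > 0)
    stop2("zero within-group variance across all groups: F undefined")
  if (sst == 0) {
    fstat <- 0                       # all observations identical
  } else {
    fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  }

  if (!is.null(seed)) set.seed(seed)
  codes <- as.integer(f)
  # Under permutation SST is fixed, so F is monotone in SSB; still compute F
  # per replicate for clarity (cheap at panel scale).
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    vp <- values[sample.int(N)]
    gs <- rowsum(vp, codes)[, 1]
    ssb_p <- sum(gs^2 / ng) - N * grand^2
    ssw_p <- sst - ssb_p
    f_p <- if (sst == 0) 0 else (ssb_p / (k - 1)) / (ssw_p / (N - k))
    if (f_p >= fstat - 1e-12) cnt <- cnt + 1L
  }
  pval <- (1 + cnt) / (n_perm + 1)

  tab <- data.frame(group = levels(f), n = ng, mean = gmean,
                    sd = vapply(split(values, f), sd, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, statistic = fstat, p.value = pval,
                 df = c(k - 1, N - k), n_perm = n_perm, seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way comparison: F(%d, %d) = %.4g, permutation p = %.4g (%d perms)\n",
              x$df[1], x$df[2], x$statistic, x$p.value, x$n_perm))
  print(x$table, row.names = FALSE)
  invisible(x)
}
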