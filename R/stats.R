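# Nonparametric statistical framework and dataset/group accounting.

test_result <- function(statistic, p_value, method, n, adjusted = FALSE) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n = n, adjusted = adjusted),
    class = "spatiodyn_test"
  )
}

#' @export
print.spatiodyn_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (x$adjusted) " (adjusted)" else ""))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus nonparametric comparison of k independent samples (tie-corrected
#' H statistic, chi-square p-value with k-1 df). When every observation is
#' identical the statistic is 0 and p = 1 by convention.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return a `spatiodyn_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 nonempty groups")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    return(test_result(0, 1, "Kruskal-Wallis", lengths(groups)))
  kt <- kruskal.test(groups)
  test_result(kt$statistic, kt$p.value, "Kruskal-Wallis", lengths(groups))
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided paired test; zero differences are dropped, ties get mid-ranks.
#' Exact p by sign-pattern enumeration for n <= `exact_max` pairs without
#' ties, normal approximation (with continuity correction) above. All
#' differences zero gives an undefined result (`NA` p) rather than 0.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for the exact distribution (default 12).
#' @return a `spatiodyn_test` (p_value `NA` when undefined).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  if (length(x) != length(y) || !length(x)) stop("x and y must be paired, nonempty")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(test_result(NA_real_, NA_real_, "Wilcoxon signed-rank", 0L))
  exact <- n <= exact_max && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = !exact)
  )
  test_result(wt$statistic, wt$p.value, "Wilcoxon signed-rank", n)
}

#' Mann-Whitney U test (two independent samples)
#'
#' Two-sided rank-sum comparison; exact for small tie-free samples
#' (min(n) <= `exact_max`), tie-corrected normal approximation otherwise.
#'
#' @param x,y nonempty numeric vectors.
#' @param exact_max exact-distribution cutoff on the smaller sample
#'   (default 8).
#' @return a `spatiodyn_test` whose statistic is U for `x` relative to `y`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  exact <- min(length(x), length(y)) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  test_result(wt$statistic, wt$p.value, "Mann-Whitney U",
              c(length(x), length(y)))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z tests on pooled-rank mean differences after a significant
#' Kruskal-Wallis result, with the standard tie correction; adjusted
#' p-values are `min(1, m * p)` with m = k(k-1)/2 comparisons.
#'
#' @param groups list of >= 3 numeric samples.
#' @return list of `spatiodyn_test`, one per pair, each carrying both the
#'   raw (`p_raw`) and Bonferroni-adjusted (`p_value`) probabilities.
#' @export
dunn_bonferroni <- function(groups) {
  k <- length(groups)
  if (k < 3)
    stop("Dunn's test is a post-hoc over >= 3 groups; use mann_whitney for 2")
  if (any(lengths(groups) == 0)) stop("empty group")
  pooled <- unlist(groups)
  n <- length(pooled)
  rk <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_len(k), times = sizes)
  mean_ranks <- tapply(rk, idx, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  m <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j]))
      z <- if (se > 0) (mean_ranks[i] - mean_ranks[j]) / se else 0
      p_raw <- 2 * pnorm(-abs(z))
      res <- test_result(z, min(1, m * p_raw),
                         sprintf("Dunn z (group %d vs %d)", i, j),
                         c(sizes[i], sizes[j]), adjusted = TRUE)
      res$p_raw <- p_raw
      out[[sprintf("%d-%d", i, j)]] <- res
    }
  }
  out
}

#' Dataset group delineation accounting
#'
#' Bookkeeping for dividing a dataset into non-overlapping groups for
#' TR-resampling comparisons: scan time per group (hours, rounded to 2
#' decimals), totals, and the resampled TR ladder `k * tr` for integer
#' `k = 2 .. k_max`.
#'
#' @param dataset_name label.
#' @param n_groups number of independent groups.
#' @param subjects_per_group subjects in each group.
#' @param scans_per_group scans pooled per group.
#' @param timepoints_per_scan timepoints in one scan.
#' @param tr native TR in seconds.
#' @param total_scans total scans in the dataset (defaults to
#'   `n_groups * scans_per_group`).
#' @param k_max largest decimation factor (default 5).
#' @return a `group_delineation` list with `scan_time_per_group_hours`,
#'   `total_timepoints`, `total_hours`, `resampled_trs` and the inputs.
#' @export
delineate_groups <- function(dataset_name, n_groups, subjects_per_group,
                             scans_per_group, timepoints_per_scan, tr,
                             total_scans = n_groups * scans_per_group,
                             k_max = 5) {
  vals <- c(n_groups, subjects_per_group, scans_per_group,
            timepoints_per_scan, tr, total_scans)
  if (any(vals <= 0)) stop("all counts and tr must be positive")
  scan_time <- round(scans_per_group * timepoints_per_scan * tr / 3600, 2)
  total_tp <- total_scans * timepoints_per_scan
  structure(
    list(dataset_name = dataset_name, n_groups = n_groups,
         subjects_per_group = subjects_per_group,
         scans_per_group = scans_per_group,
         timepoints_per_scan = timepoints_per_scan, tr = tr,
         total_scans = total_scans,
         scan_time_per_group_hours = scan_time,
         total_timepoints = total_tp,
         total_hours = round(total_tp * tr / 3600, 2),
         resampled_trs = if (k_max >= 2) tr * (2:k_max) else numeric(0)),
    class = "group_delineation"
  )
}

#' @export
print.group_delineation <- function(x, ...) {
  cat(sprintf("%s: %d groups x %d scans (%d tp, TR %g s): %.2f h/group; total %s tp / %.2f h\n",
              x$dataset_name, x$n_groups, x$scans_per_group,
              x$timepoints_per_scan, x$tr, x$scan_time_per_group_hours,
              format(x$total_timepoints, big.mark = ","), x$total_hours))
  invisible(x)
}
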