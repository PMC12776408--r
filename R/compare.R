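# Agreement metrics between methods, bands, TRs and scan lengths:
# network correlation structure of templates, DMN profiles, event-set
# alignment (modified Jaccard with cushion, precursor time-point
# analysis), template alignment, and scan-length stability curves.

#' Network-level correlation matrix of a template
#'
#' Aggregates template rows to network mean waveforms (including the
#' derived TPN row) and Pearson-correlates every pair over the window
#' columns. A constant network row yields 0 entries against all others and
#' is reported in the `degenerate` attribute.
#'
#' @param template an `st_template` (or planted template / bare matrix with
#'   ROI rownames matching `parc`).
#' @param parc a [make_parcellation()] object.
#' @return symmetric matrix \[9 x 9\] with unit diagonal, labelled SCN,
#'   LIM, SMN, VIS, VAN, DAN, FPN, TPN, DMN.
#' @export
template_network_correlations <- function(template, parc) {
  wf <- template_matrix(template)
  if (ncol(wf) < 3) stop("template window must have at least 3 columns")
  nets <- NETWORK_ORDER_WITH_TPN
  agg <- t(vapply(nets, function(net) {
    rows <- network_members(parc, net)
    colMeans(wf[rows, , drop = FALSE])
  }, numeric(ncol(wf))))
  k <- length(nets)
  out <- matrix(0, k, k, dimnames = list(nets, nets))
  degenerate <- nets[apply(agg, 1L, sd) == 0]
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- if (i == j) 1 else safe_cor(agg[i, ], agg[j, ])
    }
  }
  if (length(degenerate)) {
    out[degenerate, ] <- 0; out[, degenerate] <- 0
    diag(out)[] <- 1
    attr(out, "degenerate") <- degenerate
  }
  out
}

#' Elementwise difference of two network correlation matrices
#'
#' `a - b`; with the cPCA matrix first and the QPP matrix second, positive
#' entries mean higher correlation under cPCA.
#'
#' @param a,b network correlation matrices with identical labels.
#' @return difference matrix.
#' @export
correlation_difference <- function(a, b) {
  if (!identical(dimnames(a), dimnames(b)))
    stop("matrices have different labels or ordering")
  a - b
}

#' DMN correlation profile
#'
#' The DMN row of a network correlation matrix against the 8 other
#' networks, in fixed order SCN, LIM, SMN, VIS, VAN, DAN, FPN, TPN. This
#' is the per-template fidelity benchmark used across all sweeps.
#'
#' @param m a [template_network_correlations()] matrix.
#' @return named numeric vector of length 8, values in \[-1, 1\].
#' @export
dmn_profile <- function(m) {
  if (!"DMN" %in% rownames(m)) stop("matrix has no DMN row")
  others <- setdiff(rownames(m), "DMN")
  m["DMN", others]
}

# Maximum one-to-one matching between two sorted 1-D index sets under a
# |a_i - b_j| <= cushion constraint. For sorted sets the greedy two-pointer
# sweep attains the maximum matching (interval-graph argument; verified
# against brute force in tests). Returns index pairs.
match_events <- function(a, b, cushion) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  i <- 1L; j <- 1L
  pa <- integer(0); pb <- integer(0)
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= cushion) {
      pa <- c(pa, i); pb <- c(pb, j)
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  list(a = a, b = b, ia = pa, ib = pb)
}

#' Modified Jaccard index with temporal cushion
#'
#' Jaccard similarity between two event-time sets where events count as
#' shared if they can be matched one-to-one within `cushion` timepoints;
#' the matching maximizes the number of pairs. At cushion 0 on integer
#' sets this is the classical Jaccard index. Two empty sets have
#' similarity 1.
#'
#' @param a,b integer event-time vectors (timepoint indices).
#' @param cushion non-negative temporal tolerance in timepoints
#'   (default 8; rerun at 16 for sensitivity).
#' @return an `mji_result` list: `value` in \[0, 1\], `matched`, `cushion`.
#' @export
mji_cushion <- function(a, b, cushion = 8) {
  if (cushion < 0) stop("cushion must be >= 0")
  if (!length(a) && !length(b))
    return(structure(list(value = 1, matched = 0L, cushion = cushion),
                     class = "mji_result"))
  mt <- match_events(a, b, cushion)
  m <- length(mt$ia)
  structure(
    list(value = m / (length(a) + length(b) - m), matched = m,
         cushion = cushion),
    class = "mji_result"
  )
}

#' Precursor time-point analysis
#'
#' Mean signed time difference (`b - a`, in timepoints) between events of
#' two conditions matched one-to-one within a tolerance window. A positive
#' lag means events in `b` occur later than their counterparts in `a` (the
#' reference condition). With no matched pairs the lag is undefined (`NA`),
#' not zero.
#'
#' @param a reference event-time vector.
#' @param b comparison event-time vector.
#' @param tolerance matching window in timepoints (default 16).
#' @return a `ptpa_result` list: `mean_lag` (NA if no pairs), `n_pairs`,
#'   `tolerance`.
#' @export
ptpa <- function(a, b, tolerance = 16) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  mt <- match_events(a, b, tolerance)
  n <- length(mt$ia)
  structure(
    list(mean_lag = if (n) mean(mt$b[mt$ib] - mt$a[mt$ia]) else NA_real_,
         n_pairs = n, tolerance = tolerance),
    class = "ptpa_result"
  )
}

#' Best circular-shift alignment of two templates
#'
#' Maximum Pearson correlation between the flattened waveforms over all
#' circular column shifts of `b`. Templates with different window lengths
#' are first resampled to a common number of columns by linear
#' interpolation on the normalized window coordinate, so templates of the
#' same duration at different TRs are comparable.
#'
#' @param a,b templates (`st_template`, planted, or bare matrix).
#' @return list with `correlation` (at the best shift) and `shift`
#'   (columns of the common grid `b` was shifted by).
#' @export
align_templates <- function(a, b) {
  ma <- template_matrix(a); mb <- template_matrix(b)
  if (nrow(ma) != nrow(mb)) stop("templates have different ROI counts")
  w <- max(ncol(ma), ncol(mb))
  resample <- function(m) {
    if (ncol(m) == w) return(m)
    x0 <- (seq_len(ncol(m)) - 1) / ncol(m)
    x1 <- (seq_len(w) - 1) / w
    t(apply(m, 1L, function(row)
      approx(c(x0, 1), c(row, row[1]), xout = x1)$y))  # periodic extension
  }
  ma <- resample(ma); mb <- resample(mb)
  best <- -Inf; best_shift <- 0L
  va <- as.numeric(ma)
  for (s in 0:(w - 1L)) {
    r <- safe_cor(va, as.numeric(shift_template_columns(mb, s)))
    if (r > best) { best <- r; best_shift <- s }
  }
  list(correlation = best, shift = best_shift)
}

#' Scan-length stability of the DMN profile
#'
#' For each cumulative duration: per independent group, concatenate the
#' group's z-scored scans, truncate to `floor(duration / TR)` timepoints,
#' run the chosen method, and compute the DMN profile of the resulting
#' template. Variability across groups (SD per profile entry) quantifies
#' how much data the method needs for a stable estimate.
#'
#' @param groups list of groups; each group is a list of [roi_ts()] scans
#'   with a common TR.
#' @param durations_seconds strictly increasing cumulative durations.
#' @param method `"qpp"` or `"cpca"`.
#' @param parc a [make_parcellation()] object.
#' @param wl_seconds template window length in seconds.
#' @param seed seed forwarded to QPP start sampling.
#' @param n_starts QPP initializations per fit.
#' @return a `stability_curve` list: `durations` (those actually run),
#'   `profiles` (array duration x network x group), `mean_profile`,
#'   `group_sd` (matrices duration x network), `method`.
#' @export
stability_curve <- function(groups, durations_seconds, method = c("qpp", "cpca"),
                            parc, wl_seconds = 24, seed = 1, n_starts = 10) {
  method <- match.arg(method)
  if (is.unsorted(durations_seconds, strictly = TRUE))
    stop("durations must be strictly increasing")
  tr <- tr_of(groups[[1]][[1]])
  w <- window_length_points(wl_seconds, tr)
  concat <- lapply(groups, function(scans) {
    vals <- do.call(cbind, lapply(scans, function(s) unclass(zscore_rows(s))))
    roi_ts(vals, tr = tr, roi_labels = rownames(scans[[1]]))
  })
  nets <- setdiff(NETWORK_ORDER_WITH_TPN, "DMN")
  kept <- numeric(0)
  profiles <- list()
  for (dur in durations_seconds) {
    n_keep <- floor(dur / tr)
    if (n_keep < 2 * w) {
      warning(sprintf("duration %g s (< 2 windows) skipped", dur))
      next
    }
    prof <- vapply(concat, function(series) {
      if (n_keep > ncol(series))
        stop(sprintf("duration %g s exceeds available data", dur))
      sub <- replace_values(series, unclass(series)[, seq_len(n_keep), drop = FALSE])
      tmpl <- switch(method,
        qpp = detect_qpp(sub, wl_seconds, n_starts = n_starts, seed = seed,
                         parc = parc)$template,
        cpca = component_to_template(run_cpca(sub, n = 1), 1, w, tr = tr))
      dmn_profile(template_network_correlations(tmpl, parc))
    }, numeric(length(nets)))
    kept <- c(kept, dur)
    profiles[[length(profiles) + 1L]] <- prof
  }
  if (!length(kept)) stop("no feasible duration level")
  arr <- array(unlist(profiles),
               dim = c(length(nets), length(concat), length(kept)),
               dimnames = list(nets, NULL, NULL))
  arr <- aperm(arr, c(3, 1, 2))  # duration x network x group
  structure(
    list(durations = kept, profiles = arr,
         mean_profile = apply(arr, c(1, 2), mean),
         group_sd = apply(arr, c(1, 2), sd),
         method = method),
    class = "stability_curve"
  )
}
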