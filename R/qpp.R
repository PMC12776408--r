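# Quasi-periodic pattern (QPP) detection: iterative sliding-window
# template matching with correlation-peak guided refinement.

#' Spatiotemporal template
#'
#' A real \[n_roi x W\] waveform with its sampling interval; produced by
#' QPP detection and by cPCA component reconstruction.
#'
#' @param waveform numeric matrix \[n_roi x W\].
#' @param tr sampling interval in seconds.
#' @param source `"qpp"`, `"cpca"` or `"planted"`.
#' @return an `st_template` list with `waveform`, `window_points`,
#'   `window_seconds`, `tr`, `source`.
#' @export
st_template <- function(waveform, tr, source = "qpp") {
  waveform <- as.matrix(waveform)
  if (ncol(waveform) < 2 || any(!is.finite(waveform)))
    stop("template waveform must be a finite matrix with W >= 2 columns")
  structure(
    list(waveform = waveform, window_points = ncol(waveform),
         window_seconds = ncol(waveform) * tr, tr = tr, source = source),
    class = "st_template"
  )
}

#' @export
print.st_template <- function(x, ...) {
  cat(sprintf("<st_template:%s> %d ROIs x %d points (%.2f s at TR %g s)\n",
              x$source, nrow(x$waveform), x$window_points,
              x$window_seconds, x$tr))
  invisible(x)
}

template_matrix <- function(template) {
  if (inherits(template, "st_template")) template$waveform
  else if (inherits(template, "planted_template")) template$waveform
  else as.matrix(template)
}

# circularly shift template columns right by s (column m comes from m - s)
shift_template_columns <- function(mat, s) {
  w <- ncol(mat)
  s <- ((s %% w) + w) %% w
  if (s == 0) return(mat)
  mat[, ((seq_len(w) - 1L - s) %% w) + 1L, drop = FALSE]
}

#' Window length in timepoints
#'
#' Converts a window length in seconds to timepoints at a given TR,
#' rounding half away from zero. The canonical window is 24 s, the
#' duration at which the dominant quasi-periodic pattern is best resolved.
#'
#' @param wl_seconds window length in seconds (> 0).
#' @param tr sampling interval in seconds (> 0).
#' @return integer number of timepoints (>= 2).
#' @export
window_length_points <- function(wl_seconds, tr) {
  if (wl_seconds <= 0 || tr <= 0) stop("wl_seconds and tr must be positive")
  w <- as.integer(floor(wl_seconds / tr + 0.5))  # round half away from zero
  if (w < 2)
    stop(sprintf("window of %g s is unresolvable at TR %g s (< 2 timepoints)",
                 wl_seconds, tr))
  w
}

#' Sliding spatiotemporal correlation
#'
#' Pearson correlation between the flattened template and the flattened
#' series segment starting at every timepoint `t = 1 .. n_time - W + 1`.
#' Segments with zero variance yield a correlation of 0 at that offset.
#'
#' @param series an [roi_ts()].
#' @param template an `st_template`, `planted_template`, or bare matrix
#'   with the same number of rows as `series`.
#' @return numeric vector of length `n_time - W + 1`, values in \[-1, 1\],
#'   with attribute `tr`.
#' @export
sliding_correlation <- function(series, template) {
  tm <- template_matrix(template)
  x <- unclass(series)
  n_roi <- nrow(x); n_time <- ncol(x); w <- ncol(tm)
  if (nrow(tm) != n_roi) stop("template and series ROI counts differ")
  if (w > n_time) stop("template window exceeds series length")
  l <- n_time - w + 1L
  n <- n_roi * w
  sy <- sum(tm); syy <- sum(tm^2)
  vary <- syy - sy^2 / n
  cs <- c(0, cumsum(colSums(x)))
  cs2 <- c(0, cumsum(colSums(x^2)))
  sx <- cs[(w + 1):(n_time + 1)] - cs[1:l]
  sxx <- cs2[(w + 1):(n_time + 1)] - cs2[1:l]
  # cross term: M[m, t] = <template column m, series column t>
  m <- crossprod(tm, x)
  sxy <- numeric(l)
  for (j in seq_len(w)) sxy <- sxy + m[j, j:(j + l - 1L)]
  varx <- sxx - sx^2 / n
  num <- sxy - sx * sy / n
  den <- sqrt(pmax(varx, 0) * max(vary, 0))
  cc <- ifelse(den > 0, num / den, 0)
  cc <- pmin(1, pmax(-1, cc))
  attr(cc, "tr") <- tr_of(series)
  cc
}

#' Supra-threshold extrema of a correlation time course
#'
#' Local maxima of `c` above `+threshold` (TMX1: pattern occurrences) and
#' local minima below `-threshold` (TMX2: inverted-phase occurrences).
#' When two candidates of the same type fall closer than `min_separation`,
#' the one with larger |c| is kept (greedy suppression).
#'
#' @param c numeric correlation time course.
#' @param threshold positive correlation threshold in (0, 1).
#' @param min_separation minimum index separation within each list.
#' @return an `event_set` list: `tmx1`, `tmx2` (sorted 1-based indices),
#'   `threshold`, `min_separation`.
#' @export
find_extrema <- function(c, threshold, min_separation) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pick <- function(v, thr) {
    n <- length(v)
    if (n == 0) return(integer(0))
    left <- c(-Inf, v[-n]); right <- c(v[-1], -Inf)
    cand <- which(v > thr & v >= left & v > right)
    if (!length(cand)) return(integer(0))
    cand <- cand[order(v[cand], decreasing = TRUE)]
    keep <- integer(0)
    for (i in cand) {
      if (!length(keep) || all(abs(keep - i) >= min_separation))
        keep <- c(keep, i)
    }
    sort(keep)
  }
  structure(
    list(tmx1 = pick(as.numeric(c), threshold),
         tmx2 = pick(-as.numeric(c), threshold),
         threshold = threshold, min_separation = min_separation),
    class = "event_set"
  )
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d maxima (TMX1), %d minima (TMX2), threshold %.2f\n",
              length(x$tmx1), length(x$tmx2), x$threshold))
  invisible(x)
}

#' One QPP refinement run from a given start point
#'
#' Initializes the template from the window at `start`, then alternates
#' sliding correlation, supra-threshold maxima detection, and template
#' update (mean of the matched windows) until the correlation time course
#' stabilizes (successive-c correlation >= `tol`) or `max_iter` is
#' reached. The earlier, more permissive threshold is used for the first
#' three iterations and the stricter one afterwards.
#'
#' @param series an [roi_ts()].
#' @param start 1-based start timepoint; `start + W - 1 <= n_time`.
#' @param w window length in timepoints.
#' @param thresholds `c(tau_early, tau_late)`.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on successive correlation time courses.
#' @return list with `template` (`st_template`), `correlation` (the
#'   converged c), `events` (matched maxima of the final iteration),
#'   `history` (per-iteration event counts), `converged`.
#' @export
qpp_iterate <- function(series, start, w, thresholds = c(0.1, 0.2),
                        max_iter = 20, tol = 0.9999) {
  x <- unclass(series)
  n_time <- ncol(x)
  if (start < 1 || start + w - 1L > n_time)
    stop("start window does not fit in the series")
  # During refinement, matched windows closer than W would overlap in the
  # data and double-count the same samples in the template mean, which can
  # lock the iteration into a smeared multi-offset attractor; suppression
  # at a full window keeps the update self-consistent. Reported events use
  # the half-window separation (see find_extrema / detect_qpp).
  min_sep <- w
  tmpl <- x[, start:(start + w - 1L), drop = FALSE]
  c_prev <- NULL
  history <- integer(0)
  events <- integer(0)
  cc <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    tau <- if (iter <= 3) thresholds[1] else thresholds[2]
    cc <- sliding_correlation(series, tmpl)
    events <- find_extrema(cc, tau, min_sep)$tmx1
    if (!length(events))
      stop_spatiodyn(
        sprintf("no correlation maxima above %.2f at iteration %d; restart from another seed point", tau, iter),
        "spatiodyn_restart")
    history <- c(history, length(events))
    tmpl_new <- matrix(0, nrow(x), w)
    for (t0 in events) tmpl_new <- tmpl_new + x[, t0:(t0 + w - 1L), drop = FALSE]
    tmpl_new <- tmpl_new / length(events)
    if (!is.null(c_prev) && safe_cor(cc, c_prev) >= tol) {
      converged <- TRUE
      tmpl <- tmpl_new
      break
    }
    c_prev <- cc
    tmpl <- tmpl_new
  }
  rownames(tmpl) <- rownames(x)
  list(template = st_template(tmpl, tr = tr_of(series), source = "qpp"),
       correlation = cc, events = events,
       history = history, converged = converged)
}

#' Detect the dominant quasi-periodic pattern
#'
#' Runs [qpp_iterate()] from `n_starts` seeded random start points, keeps
#' the solution whose matched maxima carry the largest total correlation,
#' and (when a parcellation is supplied) phase-aligns the winning template
#' by circularly shifting it so the DMN-mean row attains its minimum at
#' the window centre -- the display convention under which planted and
#' detected event times coincide. Events are then re-extracted from the
#' aligned template's correlation time course at the strict threshold.
#'
#' @param series an [roi_ts()] (typically z-scored beforehand).
#' @param wl_seconds window length in seconds (default 24).
#' @param n_starts number of random initializations (default 20).
#' @param seed RNG seed for start-point sampling.
#' @param thresholds `c(tau_early, tau_late)`, defaults `c(0.1, 0.2)`.
#' @param parc optional [make_parcellation()] for phase alignment.
#' @param max_iter per-start iteration cap.
#' @return list with `template`, `correlation`, `events` (an `event_set`),
#'   `score`, `n_failed_starts`.
#' @export
detect_qpp <- function(series, wl_seconds = 24, n_starts = 20, seed = 1,
                       thresholds = c(0.1, 0.2), parc = NULL, max_iter = 20) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  w <- window_length_points(wl_seconds, tr_of(series))
  n_time <- ncol(series)
  if (n_time < 2 * w) stop("series shorter than two windows")
  starts <- with_seed(seed, sample.int(n_time - w + 1L, n_starts,
                                       replace = n_starts > n_time - w + 1L))
  min_sep <- floor(w / 2)
  best <- NULL
  n_failed <- 0L
  for (s in starts) {
    fit <- tryCatch(
      qpp_iterate(series, s, w, thresholds, max_iter),
      spatiodyn_restart = function(e) NULL
    )
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    # score on the refinement's own matched events (full-window
    # separation): totals over denser re-extractions would favour smeared
    # templates that match weakly everywhere
    ev <- fit$events
    score <- if (length(ev)) sum(fit$correlation[ev]) else -Inf
    if (is.null(best) || score > best$score) {
      best <- fit
      best$score <- score
    }
  }
  if (is.null(best) || !is.finite(best$score))
    stop("no quasi-periodic pattern found from any start point")
  align_phase <- function(tmpl) {
    if (is.null(parc)) return(tmpl)
    dmn <- colMeans(tmpl[network_members(parc, "DMN"), , drop = FALSE])
    shift_template_columns(tmpl, floor(w / 2) + 1L - which.min(dmn))
  }
  tmpl <- align_phase(best$template$waveform)
  # Rebuild once from full data windows at the aligned peaks: a template
  # that converged from a start inside an occurrence carries zero/noise
  # columns in its wrap region; averaging the actual windows at the
  # aligned event times fills them with data.
  cc <- sliding_correlation(series, tmpl)
  ev <- find_extrema(cc, thresholds[2], w)$tmx1
  if (length(ev)) {
    x <- unclass(series)
    rebuilt <- matrix(0, nrow(x), w)
    for (t0 in ev) rebuilt <- rebuilt + x[, t0:(t0 + w - 1L), drop = FALSE]
    rownames(rebuilt) <- rownames(x)
    tmpl <- align_phase(rebuilt / length(ev))
  }
  template <- st_template(tmpl, tr = tr_of(series), source = "qpp")
  cc <- sliding_correlation(series, template)
  events <- find_extrema(cc, thresholds[2], min_sep)
  list(template = template, correlation = cc, events = events,
       score = best$score, n_failed_starts = n_failed)
}
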