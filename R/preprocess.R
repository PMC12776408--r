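# Band-limiting, normalization, global signal regression, TR decimation
# and network aggregation of parcellated BOLD time series.

CANONICAL_BANDS <- list(
  "Slow-5"     = c(low = 0.01,  high = 0.027),
  "Slow-4"     = c(low = 0.027, high = 0.073),
  "Infraslow"  = c(low = 0.01,  high = 0.10),
  "Infraslow+" = c(low = 0.01,  high = 0.15)
)

#' Canonical infraslow frequency-band edges
#'
#' Returns the band edges used throughout the analyses: Slow-5
#' (0.01--0.027 Hz), Slow-4 (0.027--0.073 Hz), Infraslow (0.01--0.10 Hz)
#' and Infraslow+ (0.01--0.15 Hz). Higher bands (Slow-3, Slow-2) are
#' dominated by physiological noise at typical TRs and are deliberately
#' unsupported.
#'
#' @param name band name; also accepts lower-case aliases
#'   (`slow5`, `slow4`, `infraslow`, `infraslow_plus`).
#' @return a `frequency_band` list with `name`, `low`, `high` (Hz).
#' @export
band_limits <- function(name) {
  alias <- c(slow5 = "Slow-5", slow4 = "Slow-4",
             infraslow = "Infraslow", infraslow_plus = "Infraslow+")
  key <- if (name %in% names(alias)) alias[[name]] else name
  if (!key %in% names(CANONICAL_BANDS))
    stop(sprintf("unknown or unsupported frequency band '%s'", name))
  edges <- CANONICAL_BANDS[[key]]
  structure(list(name = key, low = unname(edges["low"]),
                 high = unname(edges["high"])),
            class = "frequency_band")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 2nd-order Butterworth band-pass forward and backward
#' (zero-phase, so filtering does not displace pattern timing) to each ROI
#' row. The band must lie strictly below the Nyquist frequency of the
#' series; an infeasible band at long TR is an error, never silently
#' clipped.
#'
#' @param series an [roi_ts()].
#' @param band a [band_limits()] object or band name.
#' @param order Butterworth order of the single-pass prototype.
#' @return filtered [roi_ts()], same shape and TR.
#' @export
bandpass_filter <- function(series, band, order = 2) {
  if (is.character(band)) band <- band_limits(band)
  tr <- tr_of(series)
  nyq <- 1 / (2 * tr)
  if (band$high >= nyq)
    stop(sprintf(
      "band '%s' upper edge %g Hz is not below Nyquist %.4g Hz at TR %g s",
      band$name, band$high, nyq, tr))
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  out <- t(apply(unclass(series), 1L,
                 function(row) signal::filtfilt(bf, row)))
  replace_values(series, out)
}

#' Z-score every ROI row
#'
#' Centers and scales each row to mean 0, SD 1. Constant rows are an error
#' (they carry no pattern information and would produce NaNs downstream).
#'
#' @param series an [roi_ts()].
#' @return standardized [roi_ts()].
#' @export
zscore_rows <- function(series) {
  v <- unclass(series)
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("constant (zero-variance) ROI row(s): ",
         paste(rownames(series)[bad], collapse = ", "))
  replace_values(series, (v - mu) / s)
}

#' Global signal regression
#'
#' Computes the global signal g(t) as the mean over ROIs and replaces every
#' row by its least-squares residual on `[1, g]`. Residual rows are
#' orthogonal to the global signal.
#'
#' @param series an [roi_ts()] with at least 2 ROIs.
#' @return residual [roi_ts()].
#' @export
global_signal_regress <- function(series) {
  v <- unclass(series)
  if (nrow(v) < 2) stop("global signal regression needs >= 2 ROIs")
  g <- colMeans(v)
  if (sd(g) == 0) stop("global signal is constant; regressor is degenerate")
  vc <- v - rowMeans(v)
  gc <- g - mean(g)
  # if the global signal is numerically negligible relative to the data
  # (input already residualized), only the mean is removed; this keeps the
  # operation idempotent instead of amplifying round-off
  if (sqrt(mean(gc^2)) < 1e-10 * sqrt(mean(vc^2)))
    return(replace_values(series, vc))
  beta <- as.numeric(vc %*% gc) / sum(gc^2)
  replace_values(series, vc - outer(beta, gc))
}

#' Decimate a series by keeping every k-th timepoint
#'
#' Emulates acquisition at an integer multiple of the native TR by
#' subsampling: columns 1, 1+k, 1+2k, ... are kept and the TR is multiplied
#' by k. No anti-alias filter is applied -- the point is to mimic what a
#' slower acquisition would have measured, faithfully including any
#' aliasing it would incur.
#'
#' @param series an [roi_ts()].
#' @param k positive integer decimation factor, `k < n_time`.
#' @return decimated [roi_ts()] with `ceil(n_time / k)` columns and TR
#'   `k * tr`.
#' @export
decimate_series <- function(series, k) {
  n_time <- ncol(series)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k >= n_time)
    stop("k must be an integer in [1, n_time)")
  k <- as.integer(k)
  if (k == 1L) return(series)
  keep <- seq(1L, n_time, by = k)
  replace_values(series, unclass(series)[, keep, drop = FALSE],
                 tr = tr_of(series) * k)
}

#' Aggregate ROI rows to network time courses
#'
#' Averages member ROI rows per base network, in fixed order SCN, LIM, SMN,
#' VIS, VAN, DAN, FPN, (TPN,) DMN. When `include_tpn` the derived
#' task-positive row (mean over DAN and FPN members) is inserted before
#' DMN.
#'
#' @param series an [roi_ts()] whose labels all appear in `parc`.
#' @param parc a [make_parcellation()] object.
#' @param include_tpn include the derived TPN row (default TRUE).
#' @return an [roi_ts()] with one row per network.
#' @export
to_networks <- function(series, parc, include_tpn = TRUE) {
  labels <- rownames(series)
  unmapped <- setdiff(labels, names(parc$network_of))
  if (length(unmapped))
    stop("ROI(s) missing from parcellation: ",
         paste(head(unmapped, 5), collapse = ", "))
  nets <- if (include_tpn) NETWORK_ORDER_WITH_TPN else BASE_NETWORKS
  v <- unclass(series)
  member_rows <- function(net) {
    members <- parc$roi_labels[network_members(parc, net)]
    which(labels %in% members)
  }
  out <- t(vapply(nets, function(net) {
    rows <- member_rows(net)
    if (!length(rows)) stop("no ROIs present for network ", net)
    colMeans(v[rows, , drop = FALSE])
  }, numeric(ncol(v))))
  roi_ts(out, tr = tr_of(series), roi_labels = nets)
}
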