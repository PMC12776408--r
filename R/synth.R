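# Synthetic-data generator: plants a known quasi-periodic propagating
# pattern in parcellated BOLD-like noise so every downstream stage has a
# ground-truth recovery target.

# Propagation ordering for traveling templates. DMN is the phase-zero
# reference (its trough sits at the window centre, the same convention
# detect_qpp() aligns to); activity then propagates through the executive
# and attention systems out to sensory and subcortical networks.
PROPAGATION_ORDER <- c("DMN", "FPN", "DAN", "VAN", "SMN", "VIS", "LIM", "SCN")

# Task-positive networks carry opposite polarity to the DMN, reproducing
# the DMN/TPN anti-correlation that defines the dominant pattern.
SIGN_OF_NETWORK <- c(DMN = 1, FPN = -1, DAN = -1, VAN = 1,
                     SMN = 1, VIS = 1, LIM = 1, SCN = 1)

#' Build a planted spatiotemporal template
#'
#' Each ROI row is one period of a Hann-windowed cosine,
#' `s * h(m) * (cos(theta_m - phi) + cos(phi) / 2)` with
#' `theta_m = 2 * pi * (m - 1) / W` and Hann envelope
#' `h = (1 - cos(theta)) / 2`, where `phi` is the ROI's phase offset and
#' `s` the network polarity (+1 DMN-aligned, -1 for DAN/FPN). The
#' `cos(phi)/2` term inside the envelope cancels the envelope-carrier
#' cross product exactly, so every row is zero-mean at every phase while
#' keeping the window edges at zero -- compact support is what prevents
#' partial-overlap sidelobes in sliding-window matching. The DMN row
#' (phase 0, polarity +1) attains its minimum at the window centre, the
#' same convention [detect_qpp()] aligns to.
#'
#' `propagation = "standing"` plants zero-lag synchrony (all phases equal);
#' `"traveling"` spaces network phases equally over `[0, max_phase_lag]`
#' along the fixed propagation ordering DMN, FPN, DAN, VAN, SMN, VIS, LIM,
#' SCN (DMN at phase 0).
#'
#' @param parc a [make_parcellation()] object.
#' @param w_true window length in timepoints (>= 4).
#' @param propagation `"standing"` or `"traveling"`.
#' @param max_phase_lag largest network phase offset in radians
#'   (traveling only).
#' @return an object of class `planted_template`: list with `waveform`
#'   \[n_roi x w_true\], `w_true`, `phase_of_roi` (radians),
#'   `sign_of_network`.
#' @export
make_template <- function(parc, w_true, propagation = c("traveling", "standing"),
                          max_phase_lag = pi / 2) {
  propagation <- match.arg(propagation)
  if (!is.numeric(w_true) || length(w_true) != 1L || w_true < 4)
    stop("w_true must be an integer >= 4")
  w_true <- as.integer(w_true)
  n_roi <- length(parc$roi_labels)
  phase_of_network <- if (propagation == "standing") {
    stats::setNames(rep(0, 8L), PROPAGATION_ORDER)
  } else {
    stats::setNames(max_phase_lag * (seq_len(8L) - 1) / 7, PROPAGATION_ORDER)
  }
  phase_of_roi <- unname(phase_of_network[parc$network_of])
  sign_of_roi <- unname(SIGN_OF_NETWORK[parc$network_of])
  theta <- 2 * pi * (seq_len(w_true) - 1L) / w_true
  hann <- (1 - cos(theta)) / 2
  waveform <- matrix(0, n_roi, w_true,
                     dimnames = list(parc$roi_labels, NULL))
  for (b in seq_len(n_roi)) {
    phi <- phase_of_roi[b]
    waveform[b, ] <- sign_of_roi[b] * hann * (cos(theta - phi) + cos(phi) / 2)
  }
  structure(
    list(waveform = waveform, w_true = w_true,
         phase_of_roi = phase_of_roi,
         sign_of_network = SIGN_OF_NETWORK,
         propagation = propagation, max_phase_lag = max_phase_lag),
    class = "planted_template"
  )
}

#' Plant template occurrences into an otherwise silent series
#'
#' Produces a zero matrix with the template waveform added starting at each
#' event index (1-based; the occurrence covers columns
#' `t .. t + w_true - 1`).
#'
#' @param template a [make_template()] object.
#' @param n_time number of timepoints in the output.
#' @param event_times sorted 1-based start indices; spacing >= `w_true`;
#'   last occurrence must fit inside `n_time`.
#' @param tr sampling interval (seconds) recorded on the output.
#' @return list with `series` (an [roi_ts()]) and `events` (the input
#'   indices, integer).
#' @export
plant_occurrences <- function(template, n_time, event_times, tr = 1) {
  w <- template$w_true
  ev <- as.integer(event_times)
  if (is.unsorted(ev, strictly = TRUE))
    stop("event_times must be strictly increasing")
  if (length(ev) && (min(ev) < 1 || max(ev) + w - 1L > n_time))
    stop(sprintf("event at %d does not fit: needs %d timepoints of %d",
                 if (min(ev) < 1) min(ev) else max(ev), w, n_time))
  if (length(ev) > 1 && any(diff(ev) < w))
    stop("events overlap: spacing must be >= w_true")
  values <- matrix(0, nrow(template$waveform), n_time,
                   dimnames = list(rownames(template$waveform), NULL))
  for (t0 in ev) {
    idx <- t0:(t0 + w - 1L)
    values[, idx] <- values[, idx] + template$waveform
  }
  list(series = roi_ts(values, tr = tr), events = ev)
}

#' Add autocorrelated noise to a series
#'
#' Adds independent AR(1) noise to every ROI row, with stationary marginal
#' standard deviation `noise_sd`. Deterministic for a fixed seed.
#'
#' @param series an [roi_ts()].
#' @param ar_coefficient lag-1 autoregressive coefficient, in `[0, 1)`.
#' @param noise_sd marginal standard deviation of the noise (signal units).
#' @param seed RNG seed.
#' @return an [roi_ts()] of the same shape.
#' @export
add_noise <- function(series, ar_coefficient, noise_sd, seed) {
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must be in [0, 1): AR(1) noise must be stationary")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(series)
  n_roi <- nrow(series)
  n_time <- ncol(series)
  noise <- with_seed(seed, {
    innov_sd <- noise_sd * sqrt(1 - ar_coefficient^2)
    e <- matrix(rnorm(n_roi * n_time, sd = innov_sd), n_roi, n_time)
    if (ar_coefficient > 0) {
      # recursive filter per row; stationary start for column 1
      e[, 1] <- rnorm(n_roi, sd = noise_sd)
      for (t in 2:n_time) e[, t] <- ar_coefficient * e[, t - 1] + e[, t]
    }
    e
  })
  replace_values(series, unclass(series) + noise)
}

#' Synthetic cohort configuration
#'
#' Defaults describe the study conditions the package is exercised under:
#' 246 ROIs over 9 networks, TR 0.72 s, 1200 timepoints (14.4 min), a
#' traveling ~24 s pattern recurring on average every 45 s (about one
#' occurrence per 30--60 s), AR(1) noise, and SNR defined as template RMS
#' over its support divided by the noise SD.
#'
#' @param n_roi,tr,n_time series geometry.
#' @param wl_true_seconds planted window length in seconds.
#' @param mean_interval_seconds mean inter-event interval.
#' @param snr signal-to-noise ratio (`Inf` = noiseless).
#' @param propagation,max_phase_lag see [make_template()].
#' @param ar_coefficient AR(1) coefficient of the noise.
#' @param network_sizes see [make_parcellation()].
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_roi = 246, tr = 0.72, n_time = 1200,
                         wl_true_seconds = 24, mean_interval_seconds = 45,
                         snr = 1, propagation = "traveling",
                         max_phase_lag = pi / 2, ar_coefficient = 0.3,
                         network_sizes = DEFAULT_NETWORK_SIZES) {
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Composes [make_parcellation()], [make_template()], randomized event
#' placement and [add_noise()]. Event times are drawn from a jittered
#' regular grid (quasi-periodic recurrence with hard minimum spacing equal
#' to the window length). The planted truth is retained alongside the noisy
#' series.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed; identical (config, seed) gives identical output.
#' @return a `synthetic_dataset` list: `series` (noisy), `clean`
#'   (noiseless), `truth_events`, `template`, `parcellation`,
#'   `noise_params`, `seed`.
#' @export
generate_dataset <- function(config = synth_config(), seed = 1) {
  parc <- make_parcellation(config$n_roi, config$network_sizes)
  w_true <- window_length_points(config$wl_true_seconds, config$tr)
  if (config$n_time < 2 * w_true)
    stop("n_time must be at least twice the planted window length")
  template <- make_template(parc, w_true, config$propagation,
                            config$max_phase_lag)
  interval <- config$mean_interval_seconds / config$tr
  if (interval < w_true)
    stop("mean inter-event interval must be >= the window length")
  events <- with_seed(seed, {
    n_slots <- floor((config$n_time - w_true) / interval) + 1L
    grid <- 1 + (seq_len(n_slots) - 1) * interval
    jitter_half <- max(0, (interval - w_true) / 2)
    ev <- round(grid + runif(n_slots, -jitter_half, jitter_half))
    ev <- as.integer(pmax(ev, 1L))
    # enforce hard minimum spacing by a forward sweep
    for (k in seq_along(ev)[-1]) {
      if (ev[k] - ev[k - 1] < w_true) ev[k] <- ev[k - 1] + w_true
    }
    ev[ev + w_true - 1L <= config$n_time]
  })
  planted <- plant_occurrences(template, config$n_time, events, tr = config$tr)
  rms <- sqrt(mean(template$waveform^2))
  noise_sd <- if (is.infinite(config$snr)) 0 else rms / config$snr
  noisy <- add_noise(planted$series, config$ar_coefficient, noise_sd,
                     seed = seed + 1L)
  structure(
    list(series = noisy, clean = planted$series, truth_events = planted$events,
         template = template, parcellation = parc,
         noise_params = list(ar_coefficient = config$ar_coefficient,
                             noise_sd = noise_sd),
         config = config, seed = seed),
    class = "synthetic_dataset"
  )
}

#' Phase-lagged sinusoid fixture
#'
#' Analytic fixture for phase-recovery checks: row `b` is
#' `cos(2*pi*freq*t*tr - phases[b])` for `t = 0 .. n_time-1`.
#'
#' @param freq common frequency in Hz; must be below Nyquist `1/(2*tr)`.
#' @param phases per-ROI phase offsets in radians.
#' @param tr sampling interval in seconds.
#' @param n_time number of timepoints.
#' @return an [roi_ts()].
#' @export
make_phase_lagged_sinusoids <- function(freq, phases, tr, n_time) {
  nyq <- 1 / (2 * tr)
  if (freq >= nyq)
    stop(sprintf("freq %g Hz is at or above Nyquist %g Hz for TR %g s",
                 freq, nyq, tr))
  t_sec <- (seq_len(n_time) - 1) * tr
  values <- t(vapply(phases, function(p) cos(2 * pi * freq * t_sec - p),
                     numeric(n_time)))
  roi_ts(values, tr = tr)
}
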