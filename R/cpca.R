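# Complex principal component analysis of the Hilbert analytic signal:
# phase-coherent spatiotemporal modes, their projections and phase delay
# maps, plus template reconstruction for cross-method comparison.

#' Analytic (complex) signal of every ROI row
#'
#' Removes each row's mean and appends the Hilbert transform as the
#' imaginary part, computed in the frequency domain: positive frequencies
#' are doubled, negative frequencies zeroed, DC (and Nyquist for even
#' length) kept. The real part of the output equals the mean-removed input
#' exactly; for an in-band sinusoid the modulus approximates the amplitude
#' away from the series edges.
#'
#' @param series an [roi_ts()] with at least 8 timepoints.
#' @return a `complex_signal` list: `z` (complex \[N x T\] matrix), `tr`.
#' @export
analytic_signal <- function(series) {
  x <- unclass(series)
  n_time <- ncol(x)
  if (n_time < 8) stop("analytic signal unreliable for fewer than 8 timepoints")
  x <- x - rowMeans(x)
  h <- numeric(n_time)
  if (n_time %% 2 == 0) {
    h[1] <- 1; h[n_time / 2 + 1] <- 1; h[2:(n_time / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n_time + 1) / 2)] <- 2
  }
  z <- t(apply(x, 1L, function(row) fft(fft(row) * h, inverse = TRUE) / n_time))
  # force the real part to the mean-removed input (removes fp round-off)
  z <- complex(real = x, imaginary = Im(z))
  dim(z) <- dim(x)
  rownames(z) <- rownames(series)
  structure(list(z = z, tr = tr_of(series)), class = "complex_signal")
}

#' Complex correlation matrix
#'
#' `R = Z Z^H / T` on (by default) unit-RMS-normalized rows, so the
#' diagonal is exactly 1. The real part measures synchronization strength
#' and the imaginary part the phase lag between regions. The result is
#' Hermitian by construction.
#'
#' @param zs a [analytic_signal()] object.
#' @param normalize scale each row to unit RMS first (default TRUE);
#'   normalization makes the matrix scale-free so datasets of different
#'   amplitude are comparable.
#' @return a `complex_corr` list: `r` (complex Hermitian \[N x N\]), `tr`.
#' @export
complex_correlation <- function(zs, normalize = TRUE) {
  z <- zs$z
  n_time <- ncol(z)
  if (n_time < 2) stop("need at least 2 timepoints")
  if (normalize) {
    rms <- sqrt(rowMeans(Mod(z)^2))
    bad <- which(rms == 0)
    if (length(bad))
      stop("zero-RMS row(s): ", paste(rownames(z)[bad], collapse = ", "))
    z <- z / rms
  }
  r <- z %*% Conj(t(z)) / n_time
  r <- (r + Conj(t(r))) / 2              # Hermitian exactly
  diag(r) <- complex(real = Re(diag(r)), imaginary = 0)
  structure(list(r = r, tr = zs$tr), class = "complex_corr")
}

#' Complex principal component decomposition
#'
#' Singular value decomposition of the complex correlation matrix,
#' retaining the first `n` left singular vectors as components. Each
#' component's arbitrary global phase is gauged so that its
#' largest-modulus entry is real and positive, making results
#' reproducible. Explained fractions are computed over all N singular
#' values.
#'
#' @param cc a [complex_correlation()] object (or bare Hermitian matrix).
#' @param n number of components to retain, `1 <= n <= N`.
#' @return a `cpca_result` list: `components` (complex \[N x n\], unit
#'   norm), `singular_values` (all N, non-increasing),
#'   `explained_fraction` (all N, sums to 1), `tr`.
#' @export
cpca_decompose <- function(cc, n = 1) {
  r <- if (inherits(cc, "complex_corr")) cc$r else as.matrix(cc)
  nn <- nrow(r)
  if (n < 1 || n > nn) stop("n must be in [1, N]")
  herm_err <- max(Mod(r - Conj(t(r))))
  if (herm_err > 1e-9)
    stop(sprintf("input is not Hermitian (max deviation %.3g)", herm_err))
  dec <- svd(r)
  u <- dec$u[, seq_len(n), drop = FALSE]
  for (k in seq_len(n)) {
    j <- which.max(Mod(u[, k]))
    ph <- u[j, k] / Mod(u[j, k])
    u[, k] <- u[, k] / ph
  }
  rownames(u) <- rownames(r)
  structure(
    list(components = u, singular_values = dec$d,
         explained_fraction = dec$d / sum(dec$d),
         n = n, tr = if (inherits(cc, "complex_corr")) cc$tr else NA_real_),
    class = "cpca_result"
  )
}

#' @export
print.cpca_result <- function(x, ...) {
  cat(sprintf("<cpca_result> %d ROIs, %d component(s) retained; top explained fraction %.3f\n",
              nrow(x$components), x$n, x$explained_fraction[1]))
  invisible(x)
}

#' Project the analytic signal onto retained components
#'
#' `A(t) = U^H Z(t)`: complex projection time courses whose modulus is the
#' amplitude envelope and whose argument is the temporal phase of each
#' component. The per-ROI spatial phase delay map is `arg U`.
#'
#' @param result a [cpca_decompose()] object.
#' @param zs a [analytic_signal()] object with matching ROI count.
#' @return list with `projections` (complex \[n x T\]), `amplitude`,
#'   `phase_timecourse` (both \[n x T\], real), `roi_phase_map`
#'   (\[N x n\], radians).
#' @export
cpca_project <- function(result, zs) {
  u <- result$components
  if (nrow(u) != nrow(zs$z))
    stop("component and signal ROI counts differ")
  a <- Conj(t(u)) %*% zs$z
  list(projections = a, amplitude = Mod(a), phase_timecourse = Arg(a),
       roi_phase_map = Arg(u))
}

#' Reconstruct a spatiotemporal template from a component
#'
#' One full cycle of the component: `template[b, m] = sigma_k *
#' Re(U[b, k] * exp(i * 2 * pi * (m - 1) / W))`, m = 1..W. A purely real
#' component yields a standing wave (all ROIs peak together); phase spread
#' across ROIs yields a traveling wave whose per-ROI peak columns are
#' ordered by `-arg U`.
#'
#' @param result a [cpca_decompose()] object.
#' @param k component index (`<= n` retained).
#' @param w window length in timepoints (>= 4).
#' @param tr sampling interval recorded on the template (defaults to the
#'   decomposition's).
#' @return an `st_template` with `source = "cpca"`.
#' @export
component_to_template <- function(result, k = 1, w, tr = result$tr) {
  if (k < 1 || k > result$n) stop("component index k out of range")
  if (w < 4) stop("w must be >= 4")
  u <- result$components[, k]
  m <- seq_len(w) - 1L
  phase <- outer(Arg(u), 2 * pi * m / w, `+`)
  waveform <- result$singular_values[k] * Mod(u) * cos(phase)
  rownames(waveform) <- rownames(result$components)
  st_template(waveform, tr = if (is.na(tr)) 1 else tr, source = "cpca")
}

#' Run the full complex PCA chain on a series
#'
#' Convenience wrapper: [analytic_signal()], [complex_correlation()],
#' [cpca_decompose()], [cpca_project()].
#'
#' @param series an [roi_ts()].
#' @param n components to retain.
#' @param normalize see [complex_correlation()].
#' @return a `cpca_result` augmented with the projection outputs of
#'   [cpca_project()].
#' @export
run_cpca <- function(series, n = 1, normalize = TRUE) {
  zs <- analytic_signal(series)
  cc <- complex_correlation(zs, normalize = normalize)
  res <- cpca_decompose(cc, n = n)
  proj <- cpca_project(res, zs)
  res[names(proj)] <- proj
  res
}
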