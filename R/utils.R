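# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Pearson correlation that returns 0 (with a warning suppressed upstream)
# when either vector is constant.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

stop_spatiodyn <- function(msg, class) {
  stop(structure(
    class = c(class, "spatiodyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Circular correlation of two angle vectors
#'
#' Fisher--Lee circular correlation coefficient between two vectors of
#' angles in radians. Used to score recovery of planted per-ROI phase
#' offsets by the phase map of a complex principal component, where both
#' quantities are only defined modulo 2*pi.
#'
#' @param a,b numeric vectors of angles (radians), equal length.
#' @return scalar in \[-1, 1\].
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ma <- atan2(mean(sin(a)), mean(cos(a)))
  mb <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - ma)
  sb <- sin(b - mb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(0)
  sum(sa * sb) / den
}
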