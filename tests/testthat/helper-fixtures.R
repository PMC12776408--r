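# Shared fixtures and independent oracles, built in code at test time.

# small 9-ROI parcellation: one ROI per network plus one extra subcortical
tiny_sizes <- c(SCN = 2, LIM = 1, SMN = 1, VIS = 1, VAN = 1,
                DAN = 1, FPN = 1, DMN = 1)
tiny_parc <- function() make_parcellation(9, tiny_sizes)

std_parc <- function() make_parcellation()

# the standard noiseless study-condition dataset (with a whisper of noise
# so that z-scoring is defined on silent-gap rows)
noiseless_prepped <- function(seed = 3) {
  ds <- generate_dataset(synth_config(snr = Inf), seed = seed)
  list(ds = ds, z = zscore_rows(add_noise(ds$clean, 0, 1e-9, seed + 500)))
}

# Brute-force maximum one-to-one matching between two index sets under a
# cushion: enumerates all injective pairings (reference oracle for the
# greedy sweep used by mji_cushion / ptpa).
brute_force_matches <- function(a, b, cushion) {
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (count + (length(a) - i + 1L) <= best) return()
    if (i > length(a)) { best <<- max(best, count); return() }
    recurse(i + 1L, used_b, count)  # leave a[i] unmatched
    for (j in seq_along(b)) {
      if (!used_b[j] && abs(a[i] - b[j]) <= cushion) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(b)), 0L)
  best
}

# Exact two-sided signed-rank p by enumeration over all 2^n sign patterns
# (distinct nonzero differences assumed), mirroring the two-sided rule of
# the exact distribution.
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Mann-Whitney p by enumeration over all rank splits.
enumerate_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2, function(ix) sum(rk[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# simple phase unwrap for projection phase ramps
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}
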