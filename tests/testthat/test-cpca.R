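test_that("analytic signal has exact real part and unit modulus on in-band cosines", {
  tr <- 0.72; n <- 2000
  s <- make_phase_lagged_sinusoids(0.05, c(0, 0), tr, n)
  zs <- analytic_signal(s)
  x <- unclass(s) - rowMeans(unclass(s))
  attr(x, "tr") <- NULL
  expect_identical(Re(zs$z), x)
  interior <- seq(round(0.1 * n), round(0.9 * n))
  expect_lt(max(abs(Mod(zs$z[1, interior]) - 1)), 0.02)

  # quadrature: sin row has phase ~ wt - pi/2
  t_sec <- (seq_len(n) - 1) * tr
  sin_row <- roi_ts(rbind(sin(2 * pi * 0.05 * t_sec), cos(2 * pi * 0.05 * t_sec)), tr = tr)
  zq <- analytic_signal(sin_row)
  ph <- Arg(zq$z[1, interior])
  expected <- (2 * pi * 0.05 * t_sec[interior] - pi / 2)
  dphi <- (ph - expected + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi)), 0.05)

  expect_error(analytic_signal(roi_ts(matrix(rnorm(12), 2, 6), tr = 1)), "8 timepoints")
})

test_that("complex correlation is Hermitian with unit diagonal and captures phase lags", {
  delta <- 0.7
  s <- make_phase_lagged_sinusoids(0.05, c(0, delta), 0.72, 4000)
  cc <- complex_correlation(analytic_signal(s))
  expect_equal(max(Mod(cc$r - Conj(t(cc$r)))), 0)
  expect_equal(unname(Re(diag(cc$r))), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(Im(diag(cc$r))), c(0, 0))
  expect_lt(abs(abs(Arg(cc$r[1, 2])) - delta), 0.02)

  set.seed(5)
  r <- complex_correlation(analytic_signal(roi_ts(matrix(rnorm(5 * 300), 5, 300), tr = 1)))$r
  expect_equal(max(Mod(r - Conj(t(r)))), 0)
  # Cauchy-Schwarz bound on the off-diagonals
  bound <- sqrt(outer(Re(diag(r)), Re(diag(r))))
  expect_true(all(Mod(r) <= bound + 1e-9))
})

test_that("decomposition recovers planted modes, gauges phase, and sums explained fractions", {
  set.seed(8)
  u <- complex(real = rnorm(6), imaginary = rnorm(6))
  u <- u / sqrt(sum(Mod(u)^2))
  dec1 <- cpca_decompose(u %*% Conj(t(u)), n = 2)
  expect_lt(dec1$singular_values[2] / dec1$singular_values[1], 1e-8)
  expect_gt(Mod(sum(Conj(dec1$components[, 1]) * u)), 1 - 1e-9)
  # gauge: largest-modulus entry is real positive
  j <- which.max(Mod(dec1$components[, 1]))
  expect_lt(abs(Arg(dec1$components[j, 1])), 1e-9)

  eye <- diag(5) + 0i
  dec2 <- cpca_decompose(eye, n = 1)
  expect_true(all(abs(dec2$singular_values - 1) < 1e-12))
  expect_equal(dec2$explained_fraction[1], 1 / 5)
  expect_equal(sum(dec2$explained_fraction), 1, tolerance = 1e-9)

  # two orthonormal complex modes with weights 0.7 / 0.3
  v <- complex(real = rnorm(6), imaginary = rnorm(6))
  v <- v - u * sum(Conj(u) * v)
  v <- v / sqrt(sum(Mod(v)^2))
  r2 <- 0.7 * u %*% Conj(t(u)) + 0.3 * v %*% Conj(t(v))
  dec3 <- cpca_decompose(r2, n = 2)
  expect_lt(max(abs(dec3$explained_fraction[1:2] - c(0.7, 0.3))), 0.05)
  expect_equal(sum(dec3$explained_fraction), 1, tolerance = 1e-9)

  expect_error(cpca_decompose(matrix(complex(real = rnorm(9)), 3, 3), 1),
               "Hermitian")
})

test_that("projections give linear phase ramps and obey the energy bound", {
  tr <- 0.72; n <- 1500; omega <- 2 * pi * 0.05
  s <- make_phase_lagged_sinusoids(0.05, c(0, 0.4, 0.9, 1.3), tr, n)
  zs <- analytic_signal(s)
  res <- cpca_decompose(complex_correlation(zs), n = 2)
  proj <- cpca_project(res, zs)
  interior <- seq(round(0.1 * n), round(0.9 * n))
  ph <- unwrap_phase(proj$phase_timecourse[1, interior])
  slope <- stats::coef(stats::lm(ph ~ seq_along(ph)))[2]
  expect_lt(abs(abs(slope) - omega * tr) / (omega * tr), 0.01)

  # energy: projection onto n components never exceeds total signal energy
  tot <- colSums(Mod(zs$z)^2)
  expect_true(all(colSums(proj$amplitude^2) <= tot + 1e-9))

  # a component orthogonal to all signal content projects to ~0
  u_perp <- cbind(c(1, -1, 0, 0) / sqrt(2)) + 0i
  u_sig <- res$components[, 1]
  u_perp <- u_perp - u_sig * sum(Conj(u_sig) * u_perp)
  u_perp <- u_perp / sqrt(sum(Mod(u_perp)^2))
  res2 <- res; res2$components <- u_perp; res2$n <- 1
  a_perp <- cpca_project(res2, zs)$amplitude
  expect_lt(max(a_perp) / max(proj$amplitude), 0.05)
})

test_that("gauge invariance: a global phase leaves invariants untouched", {
  set.seed(13)
  s <- roi_ts(matrix(rnorm(6 * 400), 6, 400), tr = 1)
  zs <- analytic_signal(s)
  zs_rot <- zs
  zs_rot$z <- zs$z * exp(1i * 0.83)
  d1 <- cpca_decompose(complex_correlation(zs), 2)
  # the correlation matrix Z Z^H is itself invariant to a global phase
  d2 <- cpca_decompose(complex_correlation(zs_rot), 2)
  expect_lt(max(abs(d1$singular_values - d2$singular_values)), 1e-9)
  p1 <- cpca_project(d1, zs)
  p2 <- cpca_project(d2, zs_rot)
  expect_lt(max(abs(p1$amplitude - p2$amplitude)), 1e-6)
  # phase differences between ROIs unchanged
  dphi1 <- diff(p1$roi_phase_map[, 1])
  dphi2 <- diff(p2$roi_phase_map[, 1])
  expect_lt(max(abs((dphi1 - dphi2 + pi) %% (2 * pi) - pi)), 1e-6)
})

test_that("component templates encode standing and traveling structure", {
  u_real <- cbind(c(0.8, 0.6)) + 0i
  res <- list(components = u_real, singular_values = c(1, 0),
              explained_fraction = c(1, 0), n = 1, tr = 1)
  class(res) <- "cpca_result"
  tm <- component_to_template(res, 1, 16)
  peaks <- apply(tm$waveform, 1, which.max)
  expect_true(all(peaks == 1))  # purely real component: standing wave

  u_anti <- cbind(c(1, -1) / sqrt(2)) + 0i  # arg = {0, pi}
  res$components <- u_anti
  tm2 <- component_to_template(res, 1, 16)
  expect_equal(cor(tm2$waveform[1, ], tm2$waveform[2, ]), -1, tolerance = 1e-12)

  expect_error(component_to_template(res, 2, 16), "out of range")
})

test_that("traveling-wave phase maps are recovered from planted data", {
  ds <- generate_dataset(synth_config(snr = 1, max_phase_lag = pi / 2), seed = 6)
  z <- zscore_rows(ds$series)
  res <- run_cpca(z, n = 1)
  sign_vec <- ds$template$sign_of_network[ds$parcellation$network_of]
  effective <- ds$template$phase_of_roi + ifelse(sign_vec < 0, pi, 0)
  rho <- circular_correlation(res$roi_phase_map[, 1], -effective)
  expect_gte(abs(rho), 0.95)
  # peak order of the reconstructed template matches the planted phase order
  tm <- component_to_template(res, 1, ds$template$w_true, tr = 0.72)
  al <- align_templates(ds$template, tm)
  expect_gte(al$correlation, 0.8)
})
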