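test_that("template network correlations reflect planted structure", {
  p <- std_parc()
  # DMN rows = -DAN rows: perfect anti-correlation entry
  w <- 20
  s_t <- sin(2 * pi * seq_len(w) / w)
  v <- matrix(rep(rnorm(w), each = 246), 246, w, byrow = FALSE)
  v <- matrix(rnorm(246 * w), 246, w)
  v[p$network_of == "DMN", ] <- rep(s_t, each = 36)
  v[p$network_of == "DAN", ] <- rep(-s_t, each = 30)
  m <- template_network_correlations(st_template(v, tr = 1), p)
  expect_equal(m["DMN", "DAN"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))

  # all networks share one waveform: all off-diagonals 1
  v2 <- matrix(rep(s_t, each = 246), 246, w)
  m2 <- template_network_correlations(st_template(v2, tr = 1), p)
  expect_true(all(abs(m2 - 1) < 1e-12))

  # planted traveling template with opposite polarity: DMN-TPN strongly negative
  tm <- make_template(p, 32, "traveling", max_phase_lag = pi / 2)
  m3 <- template_network_correlations(tm, p)
  expect_lt(m3["DMN", "TPN"], -0.5)
})

test_that("correlation differences subtract elementwise with label checks", {
  a <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("DMN", "DAN"), c("DMN", "DAN")))
  b <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = dimnames(a))
  d <- correlation_difference(a, b)
  expect_true(all(d == matrix(c(0, 0.3, 0.3, 0), 2, 2)))
  expect_equal(correlation_difference(b, a), -d)
  expect_equal(correlation_difference(a, a), 0 * a)
  bad <- b; dimnames(bad) <- list(c("DAN", "DMN"), c("DAN", "DMN"))
  expect_error(correlation_difference(a, bad), "labels")
})

test_that("DMN profile returns the 8 fixed-order entries", {
  p <- std_parc()
  tm <- make_template(p, 32)
  m <- template_network_correlations(tm, p)
  prof <- dmn_profile(m)
  expect_length(prof, 8)
  expect_identical(names(prof),
                   c("SCN", "LIM", "SMN", "VIS", "VAN", "DAN", "FPN", "TPN"))
  expect_true(all(prof >= -1 & prof <= 1))
  expect_lt(prof["DAN"], 0)  # planted anti-correlation

  ones <- matrix(1, 9, 9, dimnames = list(rownames(m), colnames(m)))
  expect_true(all(dmn_profile(ones) == 1))
  noDMN <- m[1:8, 1:8]
  expect_error(dmn_profile(noDMN), "DMN")
})

test_that("modified Jaccard with cushion matches hand cases and conventions", {
  expect_equal(mji_cushion(c(10, 50), c(10, 50), 8)$value, 1)
  r <- mji_cushion(c(10, 50), c(12, 90), 8)
  expect_identical(r$matched, 2L - 1L)
  expect_equal(r$value, 1 / 3)
  expect_equal(mji_cushion(10, 30, 8)$value, 0)
  expect_equal(mji_cushion(integer(0), integer(0), 8)$value, 1)
  expect_equal(mji_cushion(integer(0), c(1, 2), 8)$value, 0)
})

test_that("greedy matching equals brute-force maximum matching exhaustively", {
  set.seed(21)
  for (rep_i in 1:60) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    a <- sort(sample(0:49, na))
    b <- sort(sample(0:49, nb))
    cushion <- sample(0:10, 1)
    greedy <- mji_cushion(a, b, cushion)$matched
    brute <- brute_force_matches(a, b, cushion)
    expect_identical(greedy, as.integer(brute),
                     info = sprintf("a={%s} b={%s} c=%d", toString(a), toString(b), cushion))
  }
})

test_that("MJI is symmetric, monotone in cushion, and classical at cushion 0", {
  set.seed(22)
  for (rep_i in 1:20) {
    a <- sort(sample(0:80, sample(1:8, 1)))
    b <- sort(sample(0:80, sample(1:8, 1)))
    expect_equal(mji_cushion(a, b, 5)$value, mji_cushion(b, a, 5)$value)
    vals <- sapply(c(0, 2, 5, 10, 20), function(cu) mji_cushion(a, b, cu)$value)
    expect_true(all(diff(vals) >= 0))
    jac0 <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(mji_cushion(a, b, 0)$value, jac0)
  }
})

test_that("precursor time-point analysis reports signed lags or an undefined marker", {
  r <- ptpa(10, 14, tolerance = 16)
  expect_equal(r$mean_lag, 4)
  expect_identical(r$n_pairs, 1L)
  expect_equal(ptpa(c(5, 20), c(5, 20), 16)$mean_lag, 0)
  r3 <- ptpa(10, 40, 16)
  expect_true(is.na(r3$mean_lag))
  expect_identical(r3$n_pairs, 0L)
  # bound: |mean lag| never exceeds the tolerance
  set.seed(23)
  for (rep_i in 1:10) {
    a <- sort(sample(0:200, 12)); b <- sort(sample(0:200, 12))
    r4 <- ptpa(a, b, 10)
    if (r4$n_pairs > 0) expect_lte(abs(r4$mean_lag), 10)
  }
})

test_that("template alignment is shift-invariant and handles unequal windows", {
  p <- tiny_parc()
  tm <- make_template(p, 24)
  shifted <- tm$waveform[, c(8:24, 1:7)]
  al <- align_templates(tm, st_template(shifted, tr = 1))
  expect_gte(al$correlation, 0.999)
  # same waveform sampled at half resolution still aligns well
  coarse <- tm$waveform[, seq(1, 24, by = 2)]
  al2 <- align_templates(tm, st_template(coarse, tr = 2))
  expect_gte(al2$correlation, 0.95)
})

test_that("stability curves reduce to the direct profile for one full-length group", {
  ds <- generate_dataset(synth_config(n_time = 600), seed = 12)
  p <- ds$parcellation
  sc <- stability_curve(list(list(ds$series)), durations_seconds = 600 * 0.72,
                        method = "cpca", parc = p)
  direct <- run_cpca(zscore_rows(ds$series), n = 1)
  w <- window_length_points(24, 0.72)
  prof <- dmn_profile(template_network_correlations(
    component_to_template(direct, 1, w, tr = 0.72), p))
  expect_equal(sc$profiles[1, , 1], prof, tolerance = 1e-12)
  expect_true(all(is.na(sc$group_sd)))  # dispersion undefined for one group

  expect_warning(
    stability_curve(list(list(ds$series)), durations_seconds = c(10, 432),
                    method = "cpca", parc = p),
    "skipped")
})
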