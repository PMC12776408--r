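test_that("parcellation reproduces the canonical network sizes and TPN union", {
  p <- make_parcellation()
  expect_length(p$roi_labels, 246)
  counts <- table(p$network_of)
  expect_equal(unname(counts[c("DMN", "DAN", "FPN", "VAN", "VIS", "SMN", "SCN")]),
               c(36, 30, 26, 22, 34, 33, 39), ignore_attr = TRUE)
  expect_length(p$derived_groups$TPN, 56)  # |DAN| + |FPN|
  expect_setequal(p$derived_groups$TPN,
                  which(p$network_of %in% c("DAN", "FPN")))

  tp <- tiny_parc()
  expect_length(tp$roi_labels, 9)
  expect_length(tp$derived_groups$TPN, 2)
})

test_that("parcellation validates sizes and network names", {
  bad <- tiny_sizes; bad["SCN"] <- 1
  expect_error(make_parcellation(10, bad), "sum")
  expect_error(make_parcellation(10, c(tiny_sizes, XXX = 1)), "unknown")
  expect_error(make_parcellation(8, tiny_sizes[-1]), "missing")
})

test_that("planted template rows are zero-mean, tapered, and DMN/DAN anti-correlated", {
  p <- std_parc()
  for (prop in c("standing", "traveling")) {
    tm <- make_template(p, 32, prop, max_phase_lag = pi / 2)
    expect_lt(max(abs(rowMeans(tm$waveform))), 1e-9)
    # Hann-tapered support: window edges carry no signal
    expect_lt(max(abs(tm$waveform[, 1])), 1e-12)
    dmn <- colMeans(tm$waveform[which(p$network_of == "DMN"), ])
    dan <- colMeans(tm$waveform[which(p$network_of == "DAN"), ])
    expect_lt(cor(dmn, dan), 0)
  }
  expect_error(make_template(p, 3), "w_true")
})

test_that("standing templates peak together; traveling peaks follow planted phases", {
  p <- std_parc()
  st <- make_template(p, 32, "standing")
  peaks <- apply(abs(st$waveform), 1, which.max)
  expect_true(all(peaks == peaks[1]))

  tv <- make_template(p, 64, "traveling", max_phase_lag = pi / 2)
  # compare per-row extremum locations to the planted phase prediction:
  # the extremum of the tapered carrier sits near the window centre plus
  # the phase offset in columns
  w <- 64
  pos_rows <- which(tv$sign_of_network[p$network_of] > 0)
  troughs <- apply(tv$waveform[pos_rows, ], 1, which.min)
  predicted <- sapply(tv$phase_of_roi[pos_rows], function(phi) {
    theta <- 2 * pi * (seq_len(w) - 1) / w
    which.min((1 - cos(theta)) / 2 * (cos(theta - phi) + cos(phi) / 2))
  })
  expect_true(all(abs(troughs - predicted) <= 1))
  # phase order respected: DMN extremum precedes SCN extremum
  dmn_t <- median(troughs[p$network_of[pos_rows] == "DMN"])
  scn_t <- median(troughs[p$network_of[pos_rows] == "SCN"])
  expect_lt(dmn_t, scn_t)
})

test_that("plant_occurrences places the template exactly and validates events", {
  p <- tiny_parc()
  tm <- make_template(p, 10)
  out <- plant_occurrences(tm, 100, c(1, 51))
  nonzero_cols <- which(colSums(abs(unclass(out$series))) > 0)
  expect_true(all(nonzero_cols %in% c(1:10, 51:60)))
  expect_identical(out$events, c(1L, 51L))
  # ground-truth conservation: row sums are |events| x template row sums
  expect_equal(rowSums(unclass(out$series)), 2 * rowSums(tm$waveform),
               ignore_attr = TRUE)
  expect_error(plant_occurrences(tm, 100, 96), "fit")
  expect_error(plant_occurrences(tm, 100, c(1, 6)), "overlap")
})

test_that("AR(1) noise is deterministic, scaled, and autocorrelated as configured", {
  p <- tiny_parc()
  base <- roi_ts(matrix(0, 9, 10000), tr = 1)
  expect_identical(add_noise(base, 0.3, 0, 7), base)
  n1 <- add_noise(base, 0.5, 1, 7)
  n2 <- add_noise(base, 0.5, 1, 7)
  expect_identical(unclass(n1), unclass(n2))
  ac1 <- apply(unclass(n1), 1, function(r) cor(r[-1], r[-length(r)]))
  expect_true(all(abs(ac1 - 0.5) < 0.05))
  expect_true(abs(sd(unclass(n1)) - 1) < 0.05)
  expect_error(add_noise(base, 1, 1, 7), "stationary")
})

test_that("generate_dataset is deterministic and composes truth faithfully", {
  cfg <- synth_config(n_roi = 9, network_sizes = tiny_sizes, n_time = 300)
  d1 <- generate_dataset(cfg, seed = 4)
  d2 <- generate_dataset(cfg, seed = 4)
  expect_identical(unclass(d1$series), unclass(d2$series))
  expect_identical(d1$truth_events, d2$truth_events)

  clean <- generate_dataset(synth_config(n_roi = 9, network_sizes = tiny_sizes,
                                         n_time = 300, snr = Inf), seed = 4)
  expect_identical(unclass(clean$series), unclass(clean$clean))

  # expected count: 900 s of data / 45 s mean interval ~ 20 +- 6
  big <- generate_dataset(synth_config(n_time = 1250), seed = 5)  # 900 s at TR 0.72
  expect_gte(length(big$truth_events), 14)
  expect_lte(length(big$truth_events), 26)
  expect_true(all(diff(big$truth_events) >= big$template$w_true))

  # planted anti-correlation on network-aggregated clean series
  nets <- to_networks(big$clean, big$parcellation)
  expect_lt(cor(unclass(nets)["DMN", ], unclass(nets)["DAN", ]), 0)
})

test_that("phase-lagged sinusoid fixture obeys quadrature and Nyquist rules", {
  s <- make_phase_lagged_sinusoids(0.05, c(0, pi / 2), 0.72, 2000)
  v <- unclass(s)
  expect_lt(abs(cor(v[1, ], v[2, ])), 0.02)
  s2 <- make_phase_lagged_sinusoids(0.05, c(0, 0), 0.72, 2000)
  expect_equal(unclass(s2)[1, ], unclass(s2)[2, ])
  expect_error(make_phase_lagged_sinusoids(0.8, c(0, 0), 0.72, 100), "Nyquist")
})

test_that("roi_ts and event files round-trip through the TSV dialect", {
  ds <- generate_dataset(synth_config(n_roi = 9, network_sizes = tiny_sizes,
                                      n_time = 80, tr = 1, wl_true_seconds = 10,
                                      mean_interval_seconds = 20, snr = 2),
                         seed = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_roi_tsv(ds$series, tsv)
  back <- read_roi_tsv(tsv)
  expect_equal(tr_of(back), tr_of(ds$series))
  expect_equal(unclass(back), unclass(ds$series), tolerance = 1e-6)

  pf <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(ds$parcellation, pf)
  pb <- read_parcellation(pf)
  expect_identical(pb$network_of, ds$parcellation$network_of)
  expect_identical(pb$derived_groups, ds$parcellation$derived_groups)

  ef <- withr::local_tempfile(fileext = ".txt")
  write_events(ds$truth_events, ef)
  expect_identical(read_events(ef), ds$truth_events)
})
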