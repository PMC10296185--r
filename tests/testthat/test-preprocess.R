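test_that("optical_density is the log-ratio to the temporal mean", {
  expect_equal(optical_density(rep(5, 10)), rep(0, 10))
  x <- rep(10, 11); x[4] <- 1  # one decade below the mean (approximately)
  od <- optical_density(x)
  expect_equal(od[4], -log10(1 / mean(x)))
  set.seed(1)
  r <- exp(rnorm(50))
  expect_equal(optical_density(r), -log10(r / mean(r)), tolerance = 1e-12)
  expect_error(optical_density(c(1, -1, 2)), "nonpositive")
})

test_that("beer_lambert inverts the forward model", {
  ext <- preprocess_config()$extinction
  expect_equal(unname(beer_lambert(matrix(0, 5, 2), 3)),
               matrix(0, 5, 2))

  # roundtrip: forward-synthesised OD recovers the concentrations
  set.seed(2)
  hbo <- rnorm(20) * 1e-3; hbr <- rnorm(20) * 1e-3
  sep <- 3; dpf <- c(6.1, 5.9)
  od <- cbind(sep * dpf[1] * (ext[1, 1] * hbo + ext[1, 2] * hbr),
              sep * dpf[2] * (ext[2, 1] * hbo + ext[2, 2] * hbr))
  conc <- beer_lambert(od, sep, dpf, ext)
  expect_equal(unname(conc[, "HbO"]), hbo, tolerance = 1e-10)
  expect_equal(unname(conc[, "HbR"]), hbr, tolerance = 1e-10)

  # identity configuration passes OD through
  od2 <- matrix(rnorm(10), 5, 2)
  expect_equal(unname(beer_lambert(od2, 1, c(1, 1), diag(2))), od2,
               tolerance = 1e-12)
  expect_error(beer_lambert(od2, 1, c(1, 1), matrix(1, 2, 2)), "singular")
})

test_that("zscore standardises and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  z <- zscore(rnorm(100, 50, 9))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(var(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 10)), "constant")
})

test_that("wavelet_despike removes spikes and spares smooth signal", {
  expect_equal(wavelet_despike(rep(0, 64)), rep(0, 64))

  fs <- 7.81; t_len <- 1024
  t <- (seq_len(t_len) - 1) / fs
  s <- sin(2 * pi * 0.04 * t)
  expect_lt(sd(wavelet_despike(s) - s) / sd(s), 0.05)

  x <- s
  x[500] <- x[500] + 10 * sd(s)
  d <- wavelet_despike(x)
  expect_gt(1 - abs(d[500] - s[500]) / (10 * sd(s)), 0.5)
  off <- setdiff(seq_len(t_len), 495:505)
  expect_lt(sd(d[off] - x[off]) / sd(x[off]), 0.1)

  expect_error(wavelet_despike(rnorm(6)), "8 samples")
  expect_error(wavelet_despike(rnorm(64), lambda = 2), "lambda")
})

test_that("internal DWT reconstructs perfectly at odd lengths too", {
  set.seed(4)
  x <- rnorm(96)
  dec <- nirsgraph:::.dwt_periodic(x, 3)
  expect_equal(nirsgraph:::.idwt_periodic(dec), x, tolerance = 1e-10)
  # despike with tiny lambda on pure noise keeps length, stays finite
  y <- wavelet_despike(rnorm(100), lambda = 0.9)
  expect_length(y, 100)
  expect_true(all(is.finite(y)))
})

test_that("bandpass rejects DC, passes the band, kills the cardiac band", {
  fs <- 7.81
  expect_lt(max(abs(bandpass(rep(4.2, 600), fs = fs))), 1e-8)

  t <- (seq_len(4096) - 1) / fs
  mid <- 1024:3072
  in_band <- sin(2 * pi * 0.04 * t)
  g_in <- max(abs(bandpass(in_band, fs = fs)[mid]))
  expect_gt(g_in, 0.9); expect_lt(g_in, 1.1)

  cardiac <- sin(2 * pi * 1.0 * t)
  expect_lt(max(abs(bandpass(cardiac, fs = fs)[mid])), 0.1)

  expect_error(bandpass(rnorm(100), band = c(0.08, 0.01), fs = fs), "band")
  expect_error(bandpass(rnorm(100), band = c(0.01, 5), fs = fs), "band")
})

test_that("short_channel_regress orthogonalises against the shorts", {
  set.seed(5)
  sh <- rnorm(200)
  expect_lt(max(abs(short_channel_regress(sh, cbind(sh)))), 1e-10)

  # orthogonal construction: residual equals the centred long channel
  long <- rep(c(-1, 1), 100)
  shorts <- cbind(rep(c(1, 1, -1, -1), 50))  # orthogonal to `long`
  r <- short_channel_regress(long + 3, shorts)
  expect_equal(r, long - mean(long), tolerance = 1e-10)

  # noise model: residuals uncorrelated with every regressor
  S <- matrix(rnorm(600), 200, 3)
  y <- 2 * S[, 1] + rnorm(200)
  res <- short_channel_regress(y, S)
  for (j in 1:3)
    expect_lt(abs(cor(res, S[, j])), 1e-8)
  expect_warning(short_channel_regress(y, cbind(S[, 1], S[, 1])),
                 "rank-deficient")
})

test_that("preprocess_pipeline meets its output contracts", {
  cfg <- simulation_config(n_participants = 3, n_long_channels = 3,
                           n_short_channels = 2, n_frames = 256,
                           seed = 41)
  sr <- simulate_raw(cfg)
  g <- preprocess_pipeline(sr$recordings)
  expect_s3_class(g, "group_dataset")
  expect_equal(length(g$channel_ids), 3)  # long channels only
  for (p in g$participants) for (k in seq_along(g$channel_ids))
    expect_equal(var(g$data[[p]][, k]), 1, tolerance = 1e-8)

  # unequal lengths truncate to the common minimum
  recs <- sr$recordings
  recs[[2]]$intensities <- recs[[2]]$intensities[1:200, ]
  g2 <- preprocess_pipeline(recs)
  expect_equal(g2$n_frames, 200)

  # both chromophores doubles the channel set
  g3 <- preprocess_pipeline(sr$recordings,
                            preprocess_config(chromophore = "both"))
  expect_equal(length(g3$channel_ids), 6)
  expect_true(all(grepl("_Hb[OR]$", g3$channel_ids)))
})

test_that("pipeline recovers injected band-limited HbO without confounds", {
  cfg <- simulation_config(n_participants = 3, n_long_channels = 3,
                           n_short_channels = 0, n_frames = 1024,
                           event_onsets = c(20, 70), event_duration = 10,
                           responsive_channels = 1:2, effect_size = 2,
                           seed = 43)
  sr <- simulate_raw(cfg)
  g <- preprocess_pipeline(sr$recordings)
  cors <- vapply(seq_len(3), function(p) min(vapply(1:3, function(k)
    cor(g$data[[p]][, k],
        bandpass(zscore(sr$group$data[[p]][, k]), fs = cfg$fs)),
    numeric(1))), numeric(1))
  expect_gt(min(cors), 0.95)
})
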