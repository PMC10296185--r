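test_that("canonical_hrf peaks at 4-7 s, is causal and finite-support", {
  for (fs in c(7.81, 10)) {
    h <- canonical_hrf(fs)
    expect_equal(h[1], 0)
    expect_equal(max(h), 1)
    peak_s <- (which.max(h) - 1) / fs
    expect_gt(peak_s, 4); expect_lt(peak_s, 7)
    expect_lte(length(h), floor(30 * fs) + 1)
    # undershoot present around 15 s
    expect_lt(h[round(15 * fs)], 0)
  }
})

test_that("simulation_config validates onsets and channels", {
  expect_error(simulation_config(n_participants = 2), ">= 3")
  expect_error(simulation_config(ar_coefficient = 1), "\\[0, 1\\)")
  expect_error(simulation_config(n_frames = 100, fs = 10,
                                 event_onsets = 20), "onsets")
  expect_error(simulation_config(n_long_channels = 4,
                                 responsive_channels = 9,
                                 event_onsets = 5, effect_size = 1),
               "subset")
})

test_that("simulate_group is deterministic and honours its noise model", {
  cfg <- simulation_config(n_participants = 4, n_long_channels = 6,
                           n_short_channels = 2, n_frames = 2100,
                           ar_coefficient = 0.95, spatial_rho = 0.3,
                           seed = 7)
  a <- simulate_group(cfg)
  b <- simulate_group(cfg)
  expect_identical(a$group$data, b$group$data)

  x <- a$group$data[[1]]
  # stationary variance ~ 1, lag-1 autocorrelation ~ phi,
  # cross-channel correlation ~ rho (tolerances at T = 2100)
  expect_equal(mean(apply(x, 2, var)), 1, tolerance = 0.06)
  ac1 <- mean(apply(x, 2, function(v)
    cor(v[-1], v[-length(v)])))
  expect_equal(ac1, 0.95, tolerance = 0.05)
  cc <- cor(x)
  expect_equal(mean(cc[upper.tri(cc)]), 0.3, tolerance = 0.07)
})

test_that("ground truth marks the half-peak response support", {
  cfg <- simulation_config(n_participants = 3, n_long_channels = 4,
                           n_short_channels = 0, n_frames = 600,
                           event_onsets = 20, event_duration = 10,
                           responsive_channels = c(1, 3), effect_size = 2,
                           seed = 9)
  sim <- simulate_group(cfg)
  tr <- sim$truth
  expect_setequal(tr$responsive_channels, c("ch1", "ch3"))
  expect_gt(length(tr$response_frames), 0)
  # response frames start after onset (HRF delay) and the clean signal
  # there is at least half its peak
  expect_gte(min(tr$response_frames), 20 * cfg$fs)
  clean <- tr$clean_signals[, "ch1"]
  expect_true(all(clean[tr$response_frames + 1] >= 0.5 * max(clean)))
  expect_equal(max(clean), 2)  # peak = effect size (in noise-SD units)
  expect_equal(max(abs(tr$clean_signals[, "ch2"])), 0)

  # beta = 0 -> no response frames
  sim0 <- simulate_group(simulation_config(n_participants = 3,
                                           n_long_channels = 4,
                                           n_frames = 600, seed = 9))
  expect_length(sim0$truth$response_frames, 0)
})

test_that("simulate_raw is a faithful forward model", {
  cfg <- simulation_config(n_participants = 3, n_long_channels = 2,
                           n_short_channels = 1, n_frames = 128, seed = 11)
  sr <- simulate_raw(cfg)
  expect_length(sr$recordings, 3)
  r <- sr$recordings[[1]]
  expect_true(all(r$intensities > 0))
  expect_equal(ncol(r$intensities), 2 * 3)  # (2 long + 1 short) x 2 wl
  expect_equal(r$geometry$role, c("long", "long", "short"))

  # inverting the forward model recovers the injected dynamics exactly
  ext <- preprocess_config()$extinction
  od <- optical_density(r$intensities[, 1:2])
  # remove the channel-mean offset the OD referencing introduces
  conc <- beer_lambert(od, 3.0, c(6, 6), ext)
  inj <- sr$group$data[[1]][, 1] * 1e-3
  expect_equal(conc[, "HbO"] - mean(conc[, "HbO"]), inj - mean(inj),
               tolerance = 1e-9)
})
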