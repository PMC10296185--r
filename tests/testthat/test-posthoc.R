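make_series <- function(values, fs = 7.81, t0 = 0) {
  structure(list(values = values,
                 frame_indices = seq_along(values) - 1L, fs = fs, t0 = t0),
            class = "closeness_series")
}

test_that("top_frames selects the k largest with earliest-index tie-break", {
  s <- make_series(as.numeric(1:100))
  fr <- top_frames(s)
  expect_equal(fr$frames, 95:99)
  expect_equal(fr$closeness_at_threshold, 96)  # frame 95 holds value 96

  s_const <- make_series(rep(1, 100))
  expect_equal(top_frames(s_const)$frames, 0:4)

  expect_equal(length(top_frames(make_series(rnorm(101) + 10),
                                 0.9)$frames), ceiling(0.1 * 101))
  expect_error(top_frames(s, 0), "quantile")
  expect_error(top_frames(s, 1), "quantile")
})

test_that("frame_timestamps applies the hemodynamic delay correction", {
  expect_equal(frame_timestamps(0, fs = 7.81)$seconds, 0)      # clipped
  ts <- frame_timestamps(781, fs = 7.81)
  expect_equal(ts$seconds, 781 / 7.81 - 5, tolerance = 1e-12)
  expect_equal(ts$mmss, "01:35")
  expect_equal(frame_timestamps(78, fs = 7.81, hrf_delay = 0)$seconds,
               78 / 7.81, tolerance = 1e-12)
  # t0 offset propagates
  expect_equal(frame_timestamps(0, fs = 1, hrf_delay = 0, t0 = 12)$seconds,
               12)
})

test_that("channel_relevance marks exactly k channels per frame", {
  g <- make_group(n = 5, t_len = 40, c_len = 8, seed = 13)
  rel <- channel_relevance(g, top_fraction = 0.25)
  k <- ceiling(0.25 * 8)
  expect_equal(rel$k_per_frame, k)
  # frequency conservation: sum of frequencies * T = k * T exactly
  expect_equal(sum(rel$relevance_frequency) * 40, k * 40, tolerance = 1e-12)
  expect_true(all(rel$relevance_frequency >= 0 &
                    rel$relevance_frequency <= 1))
  expect_error(channel_relevance(g, top_fraction = 1), "top_fraction")
})

test_that("drop-ranking equals ascending-LOO ranking frame by frame", {
  g <- make_group(n = 4, t_len = 25, c_len = 6, seed = 17)
  rel <- channel_relevance(g, top_fraction = 0.3)
  k <- rel$k_per_frame
  full <- rel$full_series$values
  for (t in seq_len(25)) {
    by_drop <- order(-(full[t] - rel$loo_values[t, ]), seq_len(6))[1:k]
    by_loo <- order(rel$loo_values[t, ], seq_len(6))[1:k]
    expect_identical(by_drop, by_loo)
  }
})

test_that("an injected single-channel response earns top relevance", {
  cfg <- simulation_config(n_participants = 6, n_long_channels = 6,
                           n_short_channels = 0, n_frames = 300,
                           event_onsets = c(5, 20), event_duration = 8,
                           responsive_channels = 3, effect_size = 4,
                           seed = 31)
  sim <- simulate_group(cfg)
  rel <- channel_relevance(sim$group)
  expect_equal(names(which.max(rel$relevance_frequency)), "ch3")
})

test_that("top_frames is invariant to participant order and rescaling", {
  g <- make_group(n = 5, t_len = 60, c_len = 4, seed = 19)
  fr <- top_frames(closeness_series(g))$frames
  g_rev <- group_dataset(rev(g$data), fs = g$fs)
  g_scaled <- group_dataset(lapply(g$data, function(m) 3.7 * m), fs = g$fs)
  expect_equal(top_frames(closeness_series(g_rev))$frames, fr)
  expect_equal(top_frames(closeness_series(g_scaled))$frames, fr)
})
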