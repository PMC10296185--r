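test_that("frame_distance_matrix computes pairwise Euclidean distances", {
  # identical states -> zero distance; 3-4-5 triangle
  mats <- list(rbind(c(1, 2, 2), 0), rbind(c(1, 2, 2), 0),
               rbind(c(1, 2, 5), 0))
  g <- group_dataset(mats, fs = 1)
  d <- frame_distance_matrix(g, 0)
  expect_equal(d$values[1, 2], 0)
  expect_equal(d$values[1, 3], 3)

  g2 <- group_dataset(list(rbind(c(0, 0), 1), rbind(c(3, 4), 1),
                           rbind(c(0, 1), 1)), fs = 1)
  expect_equal(frame_distance_matrix(g2, 0)$values[1, 2], 5)

  # brute-force oracle on a random frame
  set.seed(7)
  g3 <- make_group(n = 5, t_len = 4, c_len = 6, seed = 7)
  d3 <- frame_distance_matrix(g3, 2)$values
  for (i in 1:5) for (j in 1:5) {
    ss <- sum((g3$data[[i]][3, ] - g3$data[[j]][3, ])^2)
    expect_equal(d3[i, j], sqrt(ss), tolerance = 1e-12)
  }
  expect_equal(d3, t(d3))
  expect_equal(unname(diag(d3)), rep(0, 5))

  expect_error(frame_distance_matrix(g3, 4), "0-based")
  expect_error(frame_distance_matrix(g3, -1), "0-based")
})

test_that("mean_closeness matches hand arithmetic and rejects degeneracy", {
  m <- matrix(2, 3, 3); diag(m) <- 0
  expect_equal(mean_closeness(m), 0.5)

  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 3; d[1, 3] <- d[3, 1] <- 4; d[2, 3] <- d[3, 2] <- 5
  expect_equal(mean_closeness(d), (2 / 7 + 2 / 8 + 2 / 9) / 3)

  z <- matrix(0, 3, 3)
  expect_error(mean_closeness(z), "degenerate")
  expect_error(mean_closeness(matrix(1, 2, 2) - diag(2)), ">= 3 nodes")
})

test_that("row-sum closeness equals the shortest-path oracle on metric input", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    d <- random_metric_matrix(n)
    expect_equal(mean_closeness(d), oracle_mean_closeness(d),
                 tolerance = 1e-10)
  }
})

test_that("closeness_series: degeneracy, scale equivariance, invariances", {
  same <- matrix(rnorm(20), 10, 2)
  expect_error(closeness_series(group_dataset(list(same, same, same),
                                              fs = 1)),
               "frame\\(s\\) 0")

  g <- make_group(n = 5, t_len = 20, c_len = 4, seed = 3)
  s1 <- closeness_series(g)$values
  expect_length(s1, 20)
  expect_true(all(is.finite(s1) & s1 > 0))

  # doubling data halves closeness
  g2 <- group_dataset(lapply(g$data, function(m) 2 * m), fs = g$fs)
  expect_equal(closeness_series(g2)$values, s1 / 2, tolerance = 1e-12)

  # participant order invariance
  g3 <- group_dataset(rev(g$data), fs = g$fs)
  expect_equal(closeness_series(g3)$values, s1, tolerance = 1e-12)

  # translation invariance: add the same vector to every participant's frame
  shift <- matrix(rnorm(20 * 4), 20, 4)
  g4 <- group_dataset(lapply(g$data, function(m) m + shift), fs = g$fs)
  expect_equal(closeness_series(g4)$values, s1, tolerance = 1e-12)
})

test_that("a discordant high-variance frame has the lowest closeness", {
  set.seed(5)
  mats <- replicate(6, matrix(rnorm(25 * 3), 25, 3), simplify = FALSE)
  for (p in seq_along(mats)) mats[[p]][13, ] <- rnorm(3, sd = 40)
  g <- group_dataset(mats, fs = 1)
  s <- closeness_series(g)$values
  expect_equal(which.min(s), 13)
})

test_that("channel exclusion drops exactly one channel", {
  g <- make_group(n = 4, t_len = 12, c_len = 3, seed = 9)
  s_ex <- closeness_series(g, exclude_channel = "ch2")$values
  g_manual <- group_dataset(lapply(g$data, function(m) m[, c(1, 3)]),
                            fs = g$fs)
  expect_equal(s_ex, closeness_series(g_manual)$values, tolerance = 1e-14)
  expect_error(closeness_series(g, exclude_channel = "nope"), "unknown")
})

test_that("group_dataset validates its invariants", {
  expect_error(group_dataset(list(matrix(0, 3, 2), matrix(0, 3, 2)), fs = 1),
               ">= 3")
  expect_error(group_dataset(list(matrix(0, 3, 2), matrix(0, 4, 2),
                                  matrix(0, 3, 2)), fs = 1), "dimensions")
  bad <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2),
              matrix(c(1, NA, 1, 1, 1, 1), 3, 2))
  expect_error(group_dataset(bad, fs = 1), "non-finite")
  expect_error(group_dataset(list(matrix(1, 3, 2), matrix(2, 3, 2),
                                  matrix(3, 3, 2)), fs = -1), "fs")
})
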