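test_that("temporal metrics match hand-enumerated runs", {
  # path 1,1,2,2,2,1 at 250 Hz: state-1 visits of length 2 and 1,
  # one state-2 visit of length 3, a 3-sample gap between state-1 visits
  tm <- compute_temporal_metrics(c(1, 1, 2, 2, 2, 1), fs = 250, K = 2)
  expect_equal(tm$fo, c(0.5, 0.5))
  expect_equal(tm$mean_lifetime_s, c(1.5, 3) / 250)
  expect_equal(tm$mean_interval_s[1], 3 / 250)
  expect_true(is.na(tm$mean_interval_s[2]))   # single visit: no interval
  expect_equal(tm$n_visits, c(2L, 1L))
})

test_that("constant and alternating paths give closed-form metrics", {
  tm <- compute_temporal_metrics(rep(2L, 1000), fs = 250, K = 3)
  expect_equal(tm$fo, c(0, 1, 0))
  expect_equal(tm$n_visits[2], 1L)
  expect_true(is.na(tm$mean_interval_s[2]))
  expect_true(all(is.na(tm$mean_lifetime_s[c(1, 3)])))  # absent, not zero

  n <- 500
  alt <- rep(c(1L, 2L), n)
  tma <- compute_temporal_metrics(alt, fs = 250, K = 2)
  expect_equal(tma$fo, c(0.5, 0.5))
  expect_equal(tma$mean_lifetime_s, c(1, 1) / 250)
  expect_equal(tma$mean_interval_s, c(1, 1) / 250)
})

test_that("occupancy conserves and label changes match visit counts", {
  set.seed(30)
  for (i in 1:10) {
    K <- sample(2:5, 1)
    path <- sample_state_path(rand_stochastic(K), 2000, seed = i)$states
    tm <- compute_temporal_metrics(path, 250, K)
    expect_equal(sum(tm$fo), 1, tolerance = 1e-10)
    expect_equal(sum(diff(path) != 0),
                 sum(tm$n_visits, na.rm = TRUE) - 1L)
    # switching rate is visits per second
    present <- !is.na(tm$n_visits)
    expect_equal(tm$switching_rate_hz[present],
                 tm$n_visits[present] / (2000 / 250))
  }
})

test_that("metrics are equivariant under state relabelling", {
  set.seed(31)
  path <- sample_state_path(rand_stochastic(3), 3000, seed = 1)$states
  perm <- c(3L, 1L, 2L)
  a <- compute_temporal_metrics(path, 250, 3)
  b <- compute_temporal_metrics(perm[path], 250, 3)
  for (col in c("fo", "mean_lifetime_s", "mean_interval_s", "n_visits"))
    expect_equal(b[[col]][perm], a[[col]])
})

test_that("paths with NA-trimmed edges and bad labels are handled", {
  p <- c(NA, NA, 1L, 1L, 2L, NA)
  tm <- compute_temporal_metrics(p, 250, 2)
  expect_equal(tm$fo, c(2 / 3, 1 / 3))
  expect_error(compute_temporal_metrics(c(1L, 5L), 250, 2), "outside")
  expect_equal(global_switching_rate(c(1, 1, 2, 1), 4), 2)
})
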