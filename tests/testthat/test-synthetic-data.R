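test_that("state path sampling follows the generating chain", {
  # absorbing chain: identity transition keeps the initial state forever
  p <- sample_state_path(diag(3), 500, fs = 250, seed = 7)
  expect_length(unique(p$states), 1)

  # uniform 2-state chain: occupancy converges to the stationary 1/2
  p <- sample_state_path(matrix(0.5, 2, 2), 1e5, seed = 11)
  fo <- tabulate(p$states, 2) / 1e5
  expect_true(all(abs(fo - 0.5) < 0.02))

  # geometric dwell: self-transition 0.99 gives mean dwell 1/(1-p) = 100
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2)
  p <- sample_state_path(A, 1e6, fs = 250, seed = 3)
  r <- rle(p$states)
  expect_lt(abs(mean(r$lengths) - 100) / 100, 0.10)

  # reproducibility and validation
  expect_identical(sample_state_path(A, 1000, seed = 5)$states,
                   sample_state_path(A, 1000, seed = 5)$states)
  bad <- matrix(c(0.5, 0.2, 0.5, 0.9), 2)   # second row sums to 1.1
  expect_error(sample_state_path(bad, 10), "row 2")
})

test_that("synthesized signals carry the planted spectral peaks", {
  fs <- 250
  path <- sample_state_path(matrix(1), fs * 120, fs, seed = 1)
  sp <- state_spec(1L, list(oscillator(20, 2, c(1, 0))), noise_sd = 0.2)
  ses <- synth_signals(list(sp), path, seed = 2,
                       channel_roles = c("STN", "CTX"))
  ws <- welch_spectra(ses$signal, ses$channel_roles, fs)
  peak <- ws$freq[which.max(ws$stn_psd)]
  expect_lte(abs(peak - 20), 0.5)
  # channel 2 got no oscillator: flat there relative to channel 1
  at20 <- ws$freq >= 19.5 & ws$freq <= 20.5
  expect_gt(mean(ws$stn_psd[at20]), 10 * mean(ws$ctx_psd[at20]))
})

test_that("coherent oscillators couple STN and CTX channels", {
  ses <- two_channel_session(freq = 22, coherent = TRUE)
  ws <- welch_spectra(ses$signal, ses$channel_roles, 250)
  expect_gt(ws$coherence[ws$freq == 22], 0.8)

  # independent realizations on the two channels stay uncoupled
  ses0 <- two_channel_session(freq = 22, coherent = FALSE)
  ws0 <- welch_spectra(ses0$signal, ses0$channel_roles, 250)
  expect_lt(ws0$coherence[ws0$freq == 22], 0.4)
})

test_that("silent state spec produces an all-zero signal", {
  path <- sample_state_path(matrix(1), 1000, 250, seed = 1)
  sp <- state_spec(1L, list(oscillator(20, 2, c(0, 0))), noise_sd = 0)
  ses <- synth_signals(list(sp), path, channel_roles = c("STN", "CTX"))
  expect_true(all(ses$signal == 0))
})

test_that("a path state without a spec is an error", {
  path <- sample_state_path(matrix(0.5, 2, 2), 100, seed = 1)
  sp <- state_spec(1L, list(oscillator(20, 2, c(1, 1))))
  expect_error(synth_signals(list(sp), path, channel_roles = c("STN", "CTX")),
               "no state_spec for state")
})

test_that("symptom scores are the planted linear map of features", {
  feats <- data.frame(a = rnorm(50), b = rnorm(50))
  # all weights zero, no noise: constant at the intercept
  s0 <- synth_symptoms(feats, symptom_model_spec(intercept = 7), seed = 1)
  expect_equal(s0, rep(7, 50))
  # single weight, no noise: exactly linear
  s1 <- synth_symptoms(feats, symptom_model_spec(weights = c(a = 2)), seed = 1)
  expect_equal(s1, 2 * feats$a)
  expect_error(
    synth_symptoms(feats, symptom_model_spec(weights = c(missing_col = 1))),
    "missing_col")
})

test_that("make_dataset yields labelled sessions and is deterministic", {
  cfg <- default_sim_config(duration_s = 120, seed = 9)
  d1 <- make_dataset(cfg)
  expect_length(d1$sessions, 4)
  labs <- vapply(d1$sessions, function(s)
    paste0(s$participant, "_", s$hemisphere), character(1))
  expect_setequal(labs, c("P01_L", "P01_R", "P02_L", "P02_R"))
  d2 <- make_dataset(cfg)
  expect_identical(d1$sessions[[3]]$signal, d2$sessions[[3]]$signal)
  expect_identical(d1$symptoms[[2]]$bradykinesia,
                   d2$symptoms[[2]]$bradykinesia)
  # wearable on the wrist opposite the recorded hemisphere
  expect_true(all(vapply(seq_len(4), function(i)
    d1$sessions[[i]]$hemisphere != d1$symptoms[[i]]$wrist_side, logical(1))))
})
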