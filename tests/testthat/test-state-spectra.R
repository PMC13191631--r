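fs <- 250

test_that("the spectral grid has 0.5 Hz spacing over 2-100 Hz", {
  x <- matrix(rnorm(2 * fs * 120), 2)
  ws <- welch_spectra(x, c("STN", "CTX"), fs)
  expect_equal(diff(ws$freq[1:2]), 0.5)
  expect_equal(range(ws$freq), c(2, 100))
  expect_true(all(ws$stn_psd >= 0) && all(ws$ctx_psd >= 0))
  expect_true(all(ws$coherence >= 0 & ws$coherence <= 1))
  # a window with fewer than 2 analysis segments cannot define coherence
  expect_error(welch_spectra(x[, 1:500, drop = FALSE], c("STN", "CTX"), fs),
               "at least 2")
})

test_that("identical STN and CTX signals are fully coherent; noise is not", {
  set.seed(20)
  x1 <- rnorm(fs * 120)
  ws <- welch_spectra(rbind(x1, x1), c("STN", "CTX"), fs)
  expect_true(all(ws$coherence >= 0.999))

  ws0 <- welch_spectra(matrix(rnorm(2 * fs * 120), 2), c("STN", "CTX"), fs)
  expect_lt(mean(ws0$coherence), 0.15)
})

test_that("Welch power of unit-variance white noise integrates to ~1", {
  set.seed(21)
  x <- matrix(rnorm(2 * fs * 120), 2)
  # full-grid check via the internal estimator (2-100 Hz covers 98/125 of
  # the white spectrum)
  ws <- welch_spectra(x, c("STN", "CTX"), fs)
  total <- sum(ws$stn_psd) * 0.5 * 125 / 98
  expect_lt(abs(total - 1), 0.10)
})

test_that("full-occupancy state mask reproduces the unmasked multitaper spectra", {
  set.seed(22)
  x <- matrix(rnorm(2 * fs * 120), 2)
  path <- rep(1L, ncol(x))
  st <- state_masked_spectra(x, path, K = 2, c("STN", "CTX"), fs)
  expect_null(st[[2]])
  ref <- multitaper_spectra(x, c("STN", "CTX"), fs)
  expect_equal(st[[1]]$stn_psd, ref$stn_psd, tolerance = 1e-12)
  expect_equal(st[[1]]$coherence, ref$coherence, tolerance = 1e-12)
})

test_that("state-masked spectra separate planted per-state peaks", {
  A <- matrix(c(0.995, 0.005, 0.005, 0.995), 2)
  path <- sample_state_path(A, fs * 120, fs, seed = 23)
  specs <- list(
    state_spec(1L, list(oscillator(20, 2, c(1, 1))), noise_sd = 0.3),
    state_spec(2L, list(oscillator(60, 4, c(1, 1))), noise_sd = 0.3))
  ses <- synth_signals(specs, path, seed = 24, channel_roles = c("STN", "CTX"))
  st <- state_masked_spectra(ses$signal, path$states, 2,
                             ses$channel_roles, fs)
  p1 <- st[[1]]$freq[which.max(st[[1]]$stn_psd)]
  p2 <- st[[2]]$freq[which.max(st[[2]]$stn_psd)]
  expect_lte(abs(p1 - 20), 0.5)
  expect_lte(abs(p2 - 60), 0.5)
})

test_that("state-specific coherence is confined to the coherent state", {
  A <- matrix(c(0.995, 0.005, 0.005, 0.995), 2)
  path <- sample_state_path(A, fs * 240, fs, seed = 25)
  specs <- list(
    state_spec(1L, list(oscillator(22, 2, c(1, 1), coherent = FALSE)),
               noise_sd = 0.3),
    state_spec(2L, list(oscillator(22, 2, c(1, 1), coherent = TRUE)),
               noise_sd = 0.3))
  ses <- synth_signals(specs, path, seed = 26, channel_roles = c("STN", "CTX"))
  st <- state_masked_spectra(ses$signal, path$states, 2,
                             ses$channel_roles, fs)
  at22 <- which(st[[2]]$freq == 22)
  expect_gte(st[[2]]$coherence[at22] - st[[1]]$coherence[at22], 0.3)
})

test_that("band features count 15 static and 15 x K state-resolved", {
  set.seed(27)
  x <- matrix(rnorm(2 * fs * 120), 2)
  ws <- welch_spectra(x, c("STN", "CTX"), fs)
  bf <- band_features(ws)
  expect_length(bf, 15)
  expect_true(all(grepl("^(stn|ctx|coh)_", names(bf))))

  st <- state_masked_spectra(x, rep(c(1L, 2L, 3L, 4L), each = ncol(x) / 4),
                             4, c("STN", "CTX"), fs)
  bf4 <- band_features(st)
  expect_length(bf4, 60)
  expect_equal(sum(grepl("^state2_", names(bf4))), 15)

  # flat spectrum: every band power equals the constant
  wsf <- ws
  wsf$stn_psd[] <- 3; wsf$ctx_psd[] <- 3; wsf$coherence[] <- 0.5
  bff <- band_features(wsf)
  expect_true(all(bff[grepl("^(stn|ctx)_", names(bff))] == 3))
  expect_true(all(bff[grepl("^coh_", names(bff))] == 0.5))
})

test_that("decile stratification averages within then across hemisphere units", {
  set.seed(28)
  base <- welch_spectra(matrix(rnorm(2 * fs * 120), 2), c("STN", "CTX"), fs)
  n <- 40
  meta <- data.frame(participant = rep(c("P01", "P02"), each = 2 * n / 4),
                     hemisphere = rep(c("L", "R", "L", "R"), each = n / 4),
                     score = rep(seq_len(n / 4), 4))
  # identical spectra everywhere: top and bottom deciles coincide, SEM 0
  spectra <- rep(list(base), n)
  d <- decile_stratified_spectra(spectra, meta)
  expect_equal(d$top_mean, d$bottom_mean)
  expect_true(all(d$top_sem == 0))

  # planted doubling of power in high-score windows shows up in the top decile
  hi <- base; hi$stn_psd <- hi$stn_psd * 2
  spectra2 <- lapply(seq_len(n), function(i)
    if (meta$score[i] >= 9) hi else base)
  d2 <- decile_stratified_spectra(spectra2, meta)
  expect_true(all(d2$top_mean >= 2 * d2$bottom_mean - 1e-12))
  expect_equal(attr(d2, "n_units"), 4)
})
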