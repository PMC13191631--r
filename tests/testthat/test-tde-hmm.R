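test_that("time-delay embedding has the documented layout and dimensions", {
  # 4 channels, lag radius 7: 60-dimensional embedded observations
  e <- tde_embed(matrix(rnorm(4 * 100), 4), L = 7)
  expect_equal(ncol(e$X), 60)
  expect_equal(nrow(e$X), 100 - 14)
  expect_equal((2 * e$L + 1) / 250, 0.060)  # 15 points span 60 ms at 250 Hz

  # hand-constructed single channel: column t is (x[t-1], x[t], x[t+1])
  e1 <- tde_embed(matrix(1:20, 1), L = 1)
  expect_equal(e1$X[1, ], c(1, 2, 3))
  expect_equal(e1$X[10, ], c(10, 11, 12))
  expect_equal(e1$raw_index, 2:19)

  # channel-major ordering: channel 1 lags then channel 2 lags
  seg <- rbind(1:10, 101:110)
  e2 <- tde_embed(seg, L = 1)
  expect_equal(e2$X[1, ], c(1, 2, 3, 101, 102, 103))

  # constant channel embeds to the constant
  e3 <- tde_embed(matrix(5, 1, 30), L = 7)
  expect_true(all(e3$X == 5))
  expect_error(tde_embed(matrix(1:10, 1), L = 5), "too short")
})

test_that("K=1 EM reduces to the sample Gaussian moments", {
  set.seed(4)
  X <- matrix(rnorm(2000 * 3), ncol = 3) %*% matrix(c(1, .5, 0, 0, 1, .2,
                                                      0, 0, 1), 3)
  m <- fit_hmm(X, K = 1, n_restarts = 1, eps = 0)
  expect_equal(as.numeric(m$means), colMeans(X), tolerance = 1e-8)
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(m$covs[, , 1], S, tolerance = 1e-8)
})

test_that("EM is deterministic per seed and log-likelihood is monotone", {
  set.seed(5)
  X <- rbind(matrix(rnorm(500 * 2), ncol = 2),
             matrix(rnorm(500 * 2, mean = 4), ncol = 2))
  m1 <- fit_hmm(X, K = 2, seed = 3, n_restarts = 2)
  m2 <- fit_hmm(X, K = 2, seed = 3, n_restarts = 2)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$transition, m2$transition)
  d <- diff(m1$loglik_trace)
  expect_true(all(d >= -1e-8 * abs(m1$loglik_trace[-1])))
})

test_that("parameters of a known 2-state Gaussian HMM are recovered", {
  # simulate directly from the model class: well-separated means
  set.seed(6)
  A <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE)
  path <- sample_state_path(A, 50000, seed = 8)$states
  X <- matrix(rnorm(50000 * 2, sd = 1), ncol = 2) +
    cbind(c(0, 4)[path], c(0, -4)[path])
  m <- fit_hmm(X, K = 2, seed = 1, n_restarts = 2)
  dec <- hmm_viterbi(m, X)
  perm <- match_states(dec, path)
  mm <- permute_states(m, perm)
  expect_lt(abs(mm$transition[1, 1] - 0.95), 0.02)
  expect_lt(abs(mm$transition[2, 2] - 0.90), 0.02)
  expect_gt(attr(perm, "agreement"), 0.95)
})

test_that("posterior marginals and Viterbi agree with exhaustive enumeration", {
  set.seed(7)
  for (rep in 1:20) {
    K <- sample(2:3, 1); T <- sample(3:7, 1)
    A <- rand_stochastic(K)
    pi0 <- runif(K) + 0.05; pi0 <- pi0 / sum(pi0)
    logB <- matrix(log(runif(T * K) + 1e-3), T, K)
    oracle <- enumerate_hmm(logB, pi0, A)
    fb <- lfpstates:::cpp_forward_backward(logB, log(pi0), log(A))
    expect_lt(max(abs(fb$gamma - oracle$posterior)), 1e-10)
    expect_lt(abs(fb$loglik - oracle$loglik), 1e-10)
    vit <- as.integer(lfpstates:::cpp_viterbi(logB, log(pi0), log(A)))
    expect_equal(vit, unname(oracle$map))
  }
})

test_that("posterior columns normalize and degenerate emissions saturate", {
  set.seed(8)
  X <- matrix(rnorm(200 * 2), ncol = 2)
  m <- suppressWarnings(fit_hmm(X, K = 2, seed = 1, n_restarts = 1, max_iter = 5))
  stc <- hmm_posterior(m, X)
  expect_true(all(abs(rowSums(stc$gamma) - 1) < 1e-8))

  # one state essentially impossible everywhere: posterior pins the other
  m$means[2, ] <- 1e4
  stc2 <- hmm_posterior(m, X)
  expect_true(all(stc2$gamma[, 1] > 1 - 1e-6))
  expect_true(all(stc2$viterbi == 1))

  expect_error(hmm_posterior(m, matrix(rnorm(30), ncol = 3)),
               "dimension")
})

test_that("identity-transition Viterbi path is constant", {
  set.seed(9)
  X <- matrix(rnorm(100 * 2), ncol = 2)
  m <- suppressWarnings(fit_hmm(X, K = 2, seed = 1, n_restarts = 1, max_iter = 3))
  m$transition <- diag(2)
  # avoid -Inf * 0 pathologies: tiny leak keeps logs finite
  m$transition <- m$transition * (1 - 1e-12) + 1e-12 / 2
  v <- hmm_viterbi(m, X)
  expect_length(unique(v), 1)
})

test_that("state matching recovers relabellings and model permutations", {
  set.seed(10)
  path <- sample(1:4, 2000, replace = TRUE)
  expect_equal(as.integer(match_states(path, path)), 1:4)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(as.integer(match_states(path, perm[path])), perm)

  X <- rbind(matrix(rnorm(800), ncol = 2),
             matrix(rnorm(800, mean = 5), ncol = 2))
  m <- fit_hmm(X, K = 2, seed = 2, n_restarts = 1, max_iter = 10)
  mp <- permute_states(m, c(2L, 1L))
  expect_equal(as.integer(match_states(m, mp)), c(2L, 1L))
  expect_error(match_states(m, fit_hmm(X, K = 1, n_restarts = 1)),
               "unequal K")
})

test_that("permuting state labels permutes all outputs consistently", {
  set.seed(11)
  X <- rbind(matrix(rnorm(600), ncol = 2),
             matrix(rnorm(600, mean = 4), ncol = 2))
  m <- fit_hmm(X, K = 2, seed = 4, n_restarts = 1, max_iter = 10)
  perm <- c(2L, 1L)
  mp <- permute_states(m, perm)
  v <- hmm_viterbi(m, X)
  vp <- hmm_viterbi(mp, X)
  expect_equal(vp, perm[v])
  g <- hmm_posterior(m, X)$gamma
  gp <- hmm_posterior(mp, X)$gamma
  expect_equal(gp[, perm[1]], g[, 1], tolerance = 1e-12)
  expect_equal(gp[, perm[2]], g[, 2], tolerance = 1e-12)
})
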