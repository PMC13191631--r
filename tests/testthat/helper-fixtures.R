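# Shared fixtures and independent oracles for the test suite.

roles4 <- c("STN", "STN", "CTX", "CTX")

# Exhaustive-path oracle: joint log-probability of every K^T state path,
# giving exact posteriors, the exact MAP path and the exact log-likelihood.
enumerate_hmm <- function(logB, pi0, A) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  jp <- apply(paths, 1, function(p) {
    lp <- log(pi0[p[1]]) + logB[1, p[1]]
    if (T > 1)
      for (t in 2:T) lp <- lp + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    lp
  })
  w <- exp(jp - max(jp))
  post <- vapply(seq_len(K), function(k)
    vapply(seq_len(T), function(t) sum(w[paths[, t] == k]), numeric(1)),
    numeric(T))
  post <- matrix(post, T, K) / rowSums(matrix(post, T, K))
  list(posterior = post,
       map = paths[which.max(jp), ],
       loglik = max(jp) + log(sum(w)))
}

# Step-up BH oracle, straight from the definition.
bh_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * alpha / m)
  n_rej <- if (length(k)) max(k) else 0L
  reject <- logical(m)
  if (n_rej > 0) reject[o[seq_len(n_rej)]] <- TRUE
  reject
}

# Random row-stochastic matrix.
rand_stochastic <- function(K) {
  A <- matrix(runif(K * K) + 0.1, K)
  A / rowSums(A)
}

# Two-channel session (1 STN + 1 CTX) carrying a single oscillation.
two_channel_session <- function(n = 250 * 120, fs = 250, freq = 20,
                                coherent = FALSE, seed = 42) {
  path <- sample_state_path(matrix(1), n, fs, seed = seed)
  sp <- state_spec(1L, list(oscillator(freq, 2, c(1, 1),
                                       coherent = coherent)),
                   noise_sd = 0.3)
  synth_signals(list(sp), path, seed = seed,
                channel_roles = c("STN", "CTX"))
}

# Minimal epoched dataset built directly (no signal needed) for testing
# the filtering rules: one participant, windows every 120 s.
toy_epochs <- function(brady, dysk = NULL, tremor = NULL,
                       participant = "P01", session = "P01_L") {
  n <- length(brady)
  structure(list(
    epochs = data.frame(
      session = session, window = seq_len(n),
      start_sample = (seq_len(n) - 1L) * 30000L + 1L,
      end_sample = seq_len(n) * 30000L,
      timestamp = seq_len(n) * 120,
      bradykinesia = brady,
      dyskinesia = dysk %||% rep(0, n),
      tremor = tremor %||% rep(0, n),
      participant = participant, hemisphere = "L",
      stringsAsFactors = FALSE),
    sessions = list(), exclusion_log = data.frame()),
    class = "epoched_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
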