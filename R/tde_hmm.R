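#' Time-delay embedding and Gaussian hidden Markov modelling
#'
#' The raw 4-channel signal is lifted into a time-delay-embedded space (a
#' symmetric window of lags around each sample, 15 points spanning 60 ms at
#' 250 Hz by default) so that the covariance of each hidden state encodes
#' oscillatory power and cross-channel coherence. A K-state HMM with full
#' multivariate-Gaussian emissions is estimated by exact Baum-Welch EM with
#' scaled forward-backward recursions; contiguous segments are treated as
#' independent sequences sharing parameters. Decoding provides smoothed
#' posterior probabilities and the exact Viterbi MAP path.
#'
#' @name tde_hmm
NULL

#' Time-delay embed one contiguous segment
#'
#' Each embedded observation stacks the signal at lags -L..+L around a
#' centre sample, channel-major: coordinates 1..(2L+1) are channel 1 at lags
#' -L..+L, then channel 2, and so on. With 4 channels and L = 7 this yields
#' 60 dimensions per time point.
#'
#' @param segment Channels x samples numeric matrix.
#' @param L Lag radius (default 7; the embedding window has 2L+1 points).
#' @return An `embedded_series`: `X` (T x D observation matrix, rows =
#'   embedded time points), `raw_index` (centre raw-sample index of each
#'   row), `L` and `n_channels`.
#' @export
tde_embed <- function(segment, L = 7) {
  segment <- as.matrix(segment)
  n_ch <- nrow(segment)
  n <- ncol(segment)
  .assert(n > 2 * L, "segment length %d too short for lag radius %d", n, L)
  Tn <- n - 2L * as.integer(L)
  D <- n_ch * (2L * as.integer(L) + 1L)
  X <- matrix(0, Tn, D)
  col <- 0L
  for (ch in seq_len(n_ch))
    for (l in -L:L) {
      col <- col + 1L
      X[, col] <- segment[ch, (L + 1 + l):(n - L + l)]
    }
  structure(list(X = X, raw_index = (L + 1L):(n - L), L = as.integer(L),
                 n_channels = n_ch),
            class = "embedded_series")
}

#' Embed every contiguous segment of a session
#'
#' @param session A [recording_session()].
#' @param L Lag radius.
#' @return List of `embedded_series`, one per segment long enough to embed
#'   (shorter segments are skipped with a message); each carries the
#'   segment's raw-sample offset so decoded paths can be aligned to the
#'   original signal.
#' @export
embed_session <- function(session, L = 7) {
  out <- list()
  for (i in seq_len(nrow(session$segments))) {
    s <- session$segments[i, 1]; e <- session$segments[i, 2]
    if (e - s + 1L <= 2L * L) {
      message(sprintf("segment %d too short to embed; skipped", i))
      next
    }
    es <- tde_embed(session$signal[, s:e, drop = FALSE], L)
    es$raw_index <- es$raw_index + s - 1L
    out[[length(out) + 1L]] <- es
  }
  out
}

obs_matrix <- function(x) {
  if (inherits(x, "embedded_series")) x$X
  else if (is.matrix(x)) x
  else stop("expected an embedded_series or observation matrix", call. = FALSE)
}

#' Fit a multivariate-Gaussian HMM by Baum-Welch EM
#'
#' Sequences are never concatenated across segment boundaries: each element
#' of `embedded` contributes its own forward-backward pass and initial-state
#' term. Means are initialized from randomly sampled data rows and
#' covariances from the pooled covariance; the best of `n_restarts` runs by
#' final log-likelihood is kept. Covariances are regularized each M-step by
#' diagonal loading `eps * trace/D`.
#'
#' @param embedded An `embedded_series`, a T x D matrix, or a list of either
#'   (one per contiguous segment, pooled across sessions).
#' @param K Number of states (default 4).
#' @param seed Integer seed controlling initialization; fixed seed gives
#'   identical fits.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of random restarts.
#' @param eps Diagonal-loading strength.
#' @param init Optional `hmm_model` (or list with `means`, `covs`,
#'   `transition`, `initial`) to warm-start EM from; when given, random
#'   initialization and restarts are skipped. Useful for the two-stage
#'   strategy of fitting a subsample first and refining on the full data.
#' @return An `hmm_model` with `means` (K x D), `covs` (D x D x K),
#'   `transition`, `initial`, the log-likelihood trace of the winning
#'   restart, and training metadata.
#' @export
fit_hmm <- function(embedded, K = 4, seed = 1, tol = 1e-6, max_iter = 100,
                    n_restarts = 5, eps = 1e-6, init = NULL) {
  if (!is.list(embedded) || inherits(embedded, "embedded_series"))
    embedded <- list(embedded)
  Xs <- lapply(embedded, obs_matrix)
  D <- ncol(Xs[[1]])
  .assert(all(vapply(Xs, ncol, integer(1)) == D),
          "all sequences must share the embedded dimension")
  .assert(K >= 1, "K must be >= 1")
  Ttot <- sum(vapply(Xs, nrow, integer(1)))
  .assert(Ttot > K, "need more observations than states")

  if (!is.null(init)) {
    .assert(nrow(init$means) == K && ncol(init$means) == D,
            "init model dimensions do not match K and D")
    best <- cpp_baum_welch(Xs, init$means, init$covs, init$transition,
                           init$initial, as.integer(max_iter), tol, eps)
    n_restarts <- 0L
  } else {
    pooled_mean <- Reduce(`+`, lapply(Xs, colSums)) / Ttot
    pooled_cov <- Reduce(`+`, lapply(Xs, function(X) {
      Xc <- sweep(X, 2, pooled_mean)
      crossprod(Xc)
    })) / Ttot
    pooled_cov <- pooled_cov + diag(eps * sum(diag(pooled_cov)) / D, D)
    best <- NULL
  }
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seed * 1000L + r, {
      rows <- sample.int(Ttot, K)
      means0 <- matrix(0, K, D)
      offs <- cumsum(c(0L, vapply(Xs, nrow, integer(1))))
      for (k in seq_len(K)) {
        s <- findInterval(rows[k] - 1L, offs)  # sequence index
        means0[k, ] <- Xs[[s]][rows[k] - offs[s], ]
      }
      means0
    })
    covs0 <- array(pooled_cov, c(D, D, K))
    A0 <- matrix(if (K > 1) 0.05 / (K - 1) else 0, K, K)
    diag(A0) <- if (K > 1) 0.95 else 1
    fit <- cpp_baum_welch(Xs, init, covs0, A0, rep(1 / K, K),
                          as.integer(max_iter), tol, eps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; model returned with convergence flag FALSE")
  structure(list(K = as.integer(K), D = as.integer(D),
                 means = best$means, covs = best$covs,
                 transition = best$transition,
                 initial = as.numeric(best$initial),
                 loglik = best$loglik,
                 loglik_trace = as.numeric(best$loglik_trace),
                 converged = best$converged, seed = seed,
                 n_obs = best$n_obs),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("hmm_model: K=%d states, D=%d dims, loglik %.2f (%s)\n",
              x$K, x$D, x$loglik,
              if (x$converged) "converged" else "not converged"))
  cat("  self-transition probabilities:",
      paste(sprintf("%.3f", diag(x$transition)), collapse = ", "), "\n")
  invisible(x)
}

check_dims <- function(model, X) {
  .assert(ncol(X) == model$D,
          "observation dimension %d does not match model dimension %d",
          ncol(X), model$D)
}

#' Smoothed state posteriors (forward-backward)
#'
#' @param model An `hmm_model`.
#' @param embedded An `embedded_series` or T x D matrix.
#' @return A `state_time_course`: `gamma` (T x K smoothed marginals, rows
#'   sum to 1), `viterbi` (the MAP path), `loglik`, and `raw_index` when the
#'   input carries one.
#' @export
hmm_posterior <- function(model, embedded) {
  X <- obs_matrix(embedded)
  check_dims(model, X)
  logB <- cpp_log_emissions(X, model$means, model$covs)
  fb <- cpp_forward_backward(logB, log(model$initial), log(model$transition))
  vit <- as.integer(cpp_viterbi(logB, log(model$initial),
                                log(model$transition)))
  structure(list(gamma = fb$gamma, viterbi = vit, loglik = fb$loglik,
                 raw_index = if (inherits(embedded, "embedded_series"))
                   embedded$raw_index),
            class = "state_time_course")
}

#' Exact Viterbi MAP state path
#'
#' @inheritParams hmm_posterior
#' @return Integer vector of state labels in 1..K; ties in the backtrace are
#'   broken toward the lowest state index.
#' @export
hmm_viterbi <- function(model, embedded) {
  X <- obs_matrix(embedded)
  check_dims(model, X)
  logB <- cpp_log_emissions(X, model$means, model$covs)
  as.integer(cpp_viterbi(logB, log(model$initial), log(model$transition)))
}

#' Decode a session into a raw-sample-aligned state path
#'
#' Viterbi-decodes every embeddable segment and places the labels at their
#' raw centre samples; samples trimmed by the embedding (L at each segment
#' edge) and unembeddable segments are `NA`.
#'
#' @param model An `hmm_model`.
#' @param session A preprocessed [recording_session()].
#' @param L Lag radius used at embedding time.
#' @return Integer vector of length `ncol(session$signal)` with `NA` where
#'   no state is defined.
#' @export
decode_session <- function(model, session, L = 7) {
  path <- rep(NA_integer_, ncol(session$signal))
  for (es in embed_session(session, L))
    path[es$raw_index] <- hmm_viterbi(model, es)
  path
}

perms <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- perms(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    rest <- seq_len(K)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Resolve HMM label switching against a reference
#'
#' Finds, by exhaustive search over permutations (K <= 8), the relabelling
#' `perm` such that `perm[a]` best matches the reference: maximal samplewise
#' agreement for state paths, maximal mean correlation between vectorized
#' state covariances for models.
#'
#' @param a Integer state path or `hmm_model`.
#' @param reference Integer state path of the same length, or `hmm_model`
#'   with the same K.
#' @param K Number of states (inferred from models; required for paths if
#'   larger than the largest observed label).
#' @return Integer permutation of 1..K, with the achieved `agreement`
#'   (proportion of matching samples, or mean covariance correlation) as an
#'   attribute.
#' @export
match_states <- function(a, reference, K = NULL) {
  is_model <- inherits(a, "hmm_model") && inherits(reference, "hmm_model")
  if (is_model) {
    .assert(a$K == reference$K, "models have unequal K (%d vs %d)",
            a$K, reference$K)
    K <- a$K
    score <- matrix(0, K, K)  # score[k, j]: a's state k against ref state j
    for (k in seq_len(K)) for (j in seq_len(K))
      score[k, j] <- stats::cor(as.numeric(a$covs[, , k]),
                                as.numeric(reference$covs[, , j]))
  } else {
    a <- as.integer(a); reference <- as.integer(reference)
    keep <- !is.na(a) & !is.na(reference)
    a <- a[keep]; reference <- reference[keep]
    .assert(length(a) == length(reference), "paths must have equal length")
    K <- K %||% max(a, reference)
    score <- matrix(0, K, K)
    tab <- table(factor(a, levels = seq_len(K)),
                 factor(reference, levels = seq_len(K)))
    score[] <- tab / length(a)
  }
  .assert(K <= 8, "exhaustive matching supported for K <= 8")
  P <- perms(K)
  vals <- vapply(seq_len(nrow(P)), function(i)
    sum(score[cbind(seq_len(K), P[i, ])]), numeric(1))
  best <- P[which.max(vals), ]
  # paths: total proportion of agreeing samples; models: mean correlation
  agr <- sum(score[cbind(seq_len(K), best)]) / (if (is_model) K else 1)
  structure(as.integer(best), agreement = agr)
}

#' Permute the state labels of a model
#'
#' `perm[k]` becomes the new label of old state k, so
#' `permute_states(m, match_states(m, ref))` aligns `m` with `ref`.
#'
#' @param model An `hmm_model`.
#' @param perm Integer permutation of 1..K.
#' @return The relabelled `hmm_model`.
#' @export
permute_states <- function(model, perm) {
  .assert(all(sort(perm) == seq_len(model$K)), "perm must be a permutation of 1..K")
  inv <- order(perm)   # new label j holds old state inv[j]
  model$means <- model$means[inv, , drop = FALSE]
  model$covs <- model$covs[, , inv, drop = FALSE]
  model$transition <- model$transition[inv, inv, drop = FALSE]
  model$initial <- model$initial[inv]
  model
}
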