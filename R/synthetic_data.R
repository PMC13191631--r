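#' Markov-switching oscillatory signal generator
#'
#' These functions simulate multichannel local field potential recordings in
#' which a hidden Markov chain switches between oscillatory network states.
#' Each state is defined by a set of stochastically driven damped resonators
#' (AR(2) processes) with controllable centre frequency and spectral
#' bandwidth; oscillators flagged as coherent share a single driving process
#' across channels, producing elevated magnitude-squared coherence at the
#' oscillator frequency. Wearable-style symptom scores are generated as
#' linear functions of per-window features with Gaussian noise, so the whole
#' analysis chain can be validated against known ground truth.
#'
#' @name synthetic_data
NULL

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe one oscillator of a latent state
#'
#' @param freq Centre frequency in Hz (must lie in (0, fs/2) at simulation).
#' @param bandwidth Approximate full width at half maximum of the spectral
#'   peak, Hz.
#' @param gains Numeric vector of per-channel output standard deviations
#'   (amplitude units); zero silences the oscillator on that channel.
#' @param coherent If `TRUE` all channels with non-zero gain share one
#'   driving noise process, so their pairwise coherence at `freq` approaches
#'   one; otherwise each channel receives an independent realization.
#' @return An `oscillator_spec` list.
#' @export
oscillator <- function(freq, bandwidth, gains, coherent = FALSE) {
  .assert(freq > 0, "oscillator freq must be positive")
  .assert(bandwidth > 0, "oscillator bandwidth must be positive")
  structure(list(freq = freq, bandwidth = bandwidth,
                 gains = as.numeric(gains), coherent = isTRUE(coherent)),
            class = "oscillator_spec")
}

#' Describe the oscillatory fingerprint of one latent state
#'
#' @param state_id Integer state label (1..K).
#' @param oscillators List of [oscillator()] specs; at least one.
#' @param noise_sd Standard deviation of the additive white measurement
#'   noise on every channel while this state is active.
#' @return A `state_spec` list.
#' @export
state_spec <- function(state_id, oscillators, noise_sd = 1) {
  .assert(length(oscillators) >= 1, "state %d needs at least one oscillator",
          state_id)
  .assert(noise_sd >= 0, "noise_sd must be non-negative")
  if (inherits(oscillators, "oscillator_spec")) oscillators <- list(oscillators)
  structure(list(state_id = as.integer(state_id), oscillators = oscillators,
                 noise_sd = noise_sd),
            class = "state_spec")
}

#' Sample a hidden state path from a Markov chain
#'
#' @param transition K x K row-stochastic transition matrix.
#' @param n_samples Number of samples to draw (at the signal sampling rate).
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; fixed seed gives a bit-identical path.
#' @param init Optional initial distribution (defaults to uniform).
#' @return A `true_path` object: integer `states`, `fs`, the generating
#'   `transition` matrix and the `seed`.
#' @export
sample_state_path <- function(transition, n_samples, fs = 250, seed = 1,
                              init = NULL) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  .assert(ncol(transition) == K, "transition matrix must be square")
  rs <- rowSums(transition)
  bad <- which(abs(rs - 1) > 1e-8 | apply(transition, 1, function(r) any(r < 0)))
  if (length(bad))
    stop(sprintf("transition matrix row %d is not a probability vector (sums to %.6f)",
                 bad[1], rs[bad[1]]), call. = FALSE)
  .assert(n_samples >= 1, "n_samples must be >= 1")
  init <- init %||% rep(1 / K, K)
  states <- with_seed(seed, {
    u <- runif(n_samples)
    cum <- t(apply(transition, 1, cumsum))
    s <- integer(n_samples)
    s[1] <- findInterval(u[1], cumsum(init)) + 1L
    for (t in 2:n_samples)
      s[t] <- findInterval(u[t], cum[s[t - 1L], ]) + 1L
    s
  })
  structure(list(states = states, fs = fs, transition = transition,
                 seed = seed),
            class = "true_path")
}

# Transition matrix with a common mean dwell time (seconds); off-diagonal
# mass split evenly among the other states.
#' @rdname sample_state_path
#' @param K Number of states.
#' @param mean_dwell_s Mean state dwell time in seconds; the self-transition
#'   probability is `1 - 1/(fs * mean_dwell_s)` (geometric dwell).
#' @export
dwell_transition <- function(K, mean_dwell_s, fs = 250) {
  p_self <- 1 - 1 / (fs * mean_dwell_s)
  .assert(p_self >= 0 && p_self < 1, "mean_dwell_s too short for fs")
  A <- matrix((1 - p_self) / (K - 1), K, K)
  diag(A) <- p_self
  A
}

# AR(2) coefficients of a damped resonator and the gain that scales its
# stationary output to unit variance.
ar2_resonator <- function(freq, bandwidth, fs) {
  r <- exp(-pi * bandwidth / fs)
  theta <- 2 * pi * freq / fs
  a1 <- 2 * r * cos(theta)
  a2 <- -r^2
  # stationary variance of AR(2) driven by unit-variance white noise
  v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  list(a = c(a1, a2), scale = 1 / sqrt(v))
}

#' Synthesize a multichannel recording from a state path
#'
#' Each oscillator runs continuously as a unit-variance AR(2) resonator and
#' contributes to the output only while its state is active (abrupt gating at
#' sample resolution, matching the Markov switching assumption). White
#' measurement noise with the active state's `noise_sd` is added per channel.
#'
#' @param state_specs List of [state_spec()] objects, one per state id
#'   appearing in `path`.
#' @param path A `true_path` from [sample_state_path()].
#' @param seed Integer seed for the driving and measurement noise.
#' @param channel_roles Character vector of per-channel roles, `"STN"` or
#'   `"CTX"`; its length fixes the channel count.
#' @param hemisphere,participant Labels stored on the session.
#' @return A [recording_session()].
#' @export
synth_signals <- function(state_specs, path, seed = 1,
                          channel_roles = c("STN", "STN", "CTX", "CTX"),
                          hemisphere = "L", participant = "P01") {
  .assert(inherits(path, "true_path"), "path must be a true_path")
  ids <- vapply(state_specs, function(s) s$state_id, integer(1))
  used <- sort(unique(path$states))
  missing_ids <- setdiff(used, ids)
  if (length(missing_ids))
    stop(sprintf("no state_spec for state(s) %s present in path",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  n_ch <- length(channel_roles)
  n <- length(path$states)
  fs <- path$fs
  for (sp in state_specs)
    for (o in sp$oscillators) {
      .assert(o$freq < fs / 2, "oscillator freq %.1f exceeds Nyquist", o$freq)
      .assert(length(o$gains) == n_ch,
              "oscillator gains length %d != channel count %d",
              length(o$gains), n_ch)
    }

  sig <- with_seed(seed, {
    x <- matrix(0, n_ch, n)
    for (sp in state_specs) {
      mask <- as.numeric(path$states == sp$state_id)
      if (!any(mask > 0)) next
      for (o in sp$oscillators) {
        res <- ar2_resonator(o$freq, o$bandwidth, fs)
        active <- which(o$gains != 0)
        if (o$coherent) {
          z <- as.numeric(filter(rnorm(n), res$a, method = "recursive")) *
            res$scale
          for (ch in active)
            x[ch, ] <- x[ch, ] + o$gains[ch] * z * mask
        } else {
          for (ch in active) {
            z <- as.numeric(filter(rnorm(n), res$a, method = "recursive")) *
              res$scale
            x[ch, ] <- x[ch, ] + o$gains[ch] * z * mask
          }
        }
      }
      if (sp$noise_sd > 0) {
        idx <- which(mask > 0)
        x[, idx] <- x[, idx] +
          matrix(rnorm(n_ch * length(idx), sd = sp$noise_sd), n_ch)
      }
    }
    x
  })
  rownames(sig) <- make_channel_names(channel_roles)
  recording_session(signal = sig, fs = fs, channel_roles = channel_roles,
                    hemisphere = hemisphere, participant = participant)
}

#' Specify a linear symptom-score model
#'
#' @param weights Named numeric vector mapping feature-column names to
#'   coefficients (score units per feature unit).
#' @param intercept Baseline score.
#' @param noise_sd Gaussian noise standard deviation, score units.
#' @param participant_offsets,hemisphere_offsets Named numeric vectors of
#'   additive offsets (score units), looked up by the `participant` /
#'   `hemisphere` columns of the feature table when present.
#' @return A `symptom_model_spec` list.
#' @export
symptom_model_spec <- function(weights = numeric(), intercept = 0,
                               noise_sd = 0, participant_offsets = numeric(),
                               hemisphere_offsets = numeric()) {
  .assert(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(weights = weights, intercept = intercept,
                 noise_sd = noise_sd,
                 participant_offsets = participant_offsets,
                 hemisphere_offsets = hemisphere_offsets),
            class = "symptom_model_spec")
}

#' Generate symptom scores from a per-window feature table
#'
#' Score per window = intercept + sum(weight * feature) + participant and
#' hemisphere offsets + Gaussian noise.
#'
#' @param features Data frame with one row per 2-min window; must contain
#'   every column named in `spec$weights`.
#' @param spec A [symptom_model_spec()].
#' @param seed Integer seed for the noise.
#' @return Numeric vector of scores, one per row of `features`.
#' @export
synth_symptoms <- function(features, spec, seed = 1) {
  .assert(inherits(spec, "symptom_model_spec"), "spec must be a symptom_model_spec")
  missing_cols <- setdiff(names(spec$weights), names(features))
  if (length(missing_cols))
    stop(sprintf("feature column(s) missing from table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  n <- nrow(features)
  y <- rep(spec$intercept, n)
  for (nm in names(spec$weights))
    y <- y + spec$weights[[nm]] * features[[nm]]
  if (length(spec$participant_offsets) && "participant" %in% names(features))
    y <- y + unname(spec$participant_offsets[as.character(features$participant)])
  if (length(spec$hemisphere_offsets) && "hemisphere" %in% names(features))
    y <- y + unname(spec$hemisphere_offsets[as.character(features$hemisphere)])
  if (spec$noise_sd > 0)
    y <- y + with_seed(seed, rnorm(n, sd = spec$noise_sd))
  as.numeric(y)
}

#' Default simulation configuration
#'
#' Four latent states with distinct beta / gamma / coherence fingerprints
#' drawn from the phenomenology of cortico-subthalamic recordings in
#' Parkinson's disease:
#' \itemize{
#'   \item State 1: uncoupled STN beta (24 Hz) and cortical beta (18 Hz),
#'     no inter-regional coherence.
#'   \item State 2: coherent high-beta (27 Hz) across STN and cortex plus
#'     local STN low-gamma (55 Hz).
#'   \item State 3: local STN gamma (65 Hz) and broad delta/alpha (6 Hz).
#'   \item State 4: local STN low-beta (15 Hz) plus coherent high-gamma
#'     (80 Hz) across STN and cortex.
#' }
#' Mean dwell time is 1 s, sessions are 20 min at 250 Hz, and two
#' participants x two hemispheres give four sessions. Bradykinesia scores
#' load positively on state-2 fractional occupancy and negatively on
#' state-1 fractional occupancy.
#'
#' @param n_participants,n_hemispheres,duration_s,fs,mean_dwell_s,seed
#'   Override individual dimensions of the default design.
#' @return A named list accepted by [make_dataset()].
#' @export
default_sim_config <- function(n_participants = 2, n_hemispheres = 2,
                               duration_s = 1200, fs = 250,
                               mean_dwell_s = 1, seed = 1) {
  osc <- oscillator
  specs <- list(
    state_spec(1L, list(
      osc(24, 3, c(1.2, 1.0, 0, 0)),
      osc(18, 3, c(0, 0, 1.0, 0.8))
    ), noise_sd = 1),
    state_spec(2L, list(
      osc(27, 3, c(1.2, 0.6, 1.2, 0.6), coherent = TRUE),
      osc(55, 8, c(0.9, 0.9, 0, 0))
    ), noise_sd = 1),
    state_spec(3L, list(
      osc(65, 8, c(1.0, 0.8, 0, 0)),
      osc(6, 2, c(0.8, 0.8, 0.8, 0.8))
    ), noise_sd = 1),
    state_spec(4L, list(
      osc(15, 3, c(1.1, 0.9, 0, 0)),
      osc(80, 8, c(0.8, 0.5, 0.8, 0.5), coherent = TRUE)
    ), noise_sd = 1)
  )
  list(
    fs = fs, n_states = 4L, state_specs = specs,
    mean_dwell_s = mean_dwell_s, duration_s = duration_s,
    participants = sprintf("P%02d", seq_len(n_participants)),
    hemispheres = c("L", "R")[seq_len(n_hemispheres)],
    channel_roles = c("STN", "STN", "CTX", "CTX"),
    symptoms = list(
      bradykinesia = symptom_model_spec(
        weights = c(fo_state2 = 40, fo_state1 = -30), intercept = 40,
        noise_sd = 5,
        participant_offsets = c(P01 = 0, P02 = 6, P03 = -4, P04 = 2),
        hemisphere_offsets = c(L = 0, R = 2)),
      dyskinesia = symptom_model_spec(
        weights = c(fo_state4 = 25), intercept = 5, noise_sd = 3,
        participant_offsets = c(P01 = 0, P02 = 2, P03 = 1, P04 = 0)),
      tremor = symptom_model_spec(
        weights = c(fo_state3 = 30), intercept = -5, noise_sd = 3)
    ),
    seed = seed
  )
}

#' Simulate a multi-participant dataset with ground truth
#'
#' Generates one recording session per participant x hemisphere, each with
#' its own Markov state path, plus 2-min symptom scores driven by the true
#' per-window state fractional occupancies. Tremor scores are truncated at
#' zero (the wearable reports zero when no tremor is detected).
#'
#' @param config List as produced by [default_sim_config()].
#' @return A list with `sessions`, `symptoms` (one `symptom_series` per
#'   session), `paths` (the true state paths), `features` (the true
#'   per-window fractional-occupancy table) and the `config`.
#' @export
make_dataset <- function(config = default_sim_config()) {
  fs <- config$fs
  K <- config$n_states
  A <- config$transition %||% dwell_transition(K, config$mean_dwell_s, fs)
  n <- round(config$duration_s * fs)
  win <- 120 * fs
  n_win <- floor(n / win)
  .assert(n_win >= 1, "duration_s must cover at least one 2-min window")

  sessions <- list(); paths <- list(); symptoms <- list()
  feats_all <- list()
  idx <- 0L
  for (p in config$participants) for (h in config$hemispheres) {
    idx <- idx + 1L
    seed_s <- config$seed * 1000L + idx
    path <- sample_state_path(A, n, fs, seed = seed_s)
    ses <- synth_signals(config$state_specs, path, seed = seed_s + 500L,
                         channel_roles = config$channel_roles,
                         hemisphere = h, participant = p)
    # ground-truth per-window fractional occupancies
    fo <- t(vapply(seq_len(n_win), function(w) {
      seg <- path$states[((w - 1L) * win + 1L):(w * win)]
      tabulate(seg, nbins = K) / win
    }, numeric(K)))
    colnames(fo) <- sprintf("fo_state%d", seq_len(K))
    feats <- data.frame(participant = p, hemisphere = h,
                        window = seq_len(n_win), fo,
                        stringsAsFactors = FALSE)
    scores <- lapply(seq_along(config$symptoms), function(j) {
      synth_symptoms(feats, config$symptoms[[j]],
                     seed = seed_s + 700L + j)
    })
    names(scores) <- names(config$symptoms)
    if (!is.null(scores$tremor)) scores$tremor <- pmax(scores$tremor, 0)
    ts_end <- seq_len(n_win) * 120
    sym <- symptom_series(timestamps = ts_end,
                          bradykinesia = scores$bradykinesia,
                          dyskinesia = scores$dyskinesia %||% rep(0, n_win),
                          tremor = scores$tremor %||% rep(0, n_win),
                          wrist_side = if (h == "L") "R" else "L")
    sessions[[idx]] <- ses
    paths[[idx]] <- path
    symptoms[[idx]] <- sym
    feats_all[[idx]] <- feats
  }
  list(sessions = sessions, symptoms = symptoms, paths = paths,
       features = do.call(rbind, feats_all), config = config)
}
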