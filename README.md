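# lfpstates

Dynamic neural-state analysis of chronic cortico-subthalamic recordings.

People with Parkinson's disease implanted with sensing-enabled deep-brain-
stimulation systems generate weeks of 4-channel local field potentials
(two subthalamic and two motor-cortex bipolar contact pairs per hemisphere,
250 Hz) together with wrist-wearable scores of bradykinesia, dyskinesia and
tremor every 2 minutes. `lfpstates` is an R package for asking which
*transient network states* of that circuit — not just time-averaged band
power — carry motor-symptom information:

1. **State discovery.** Signals are time-delay embedded (symmetric 15-point
   lag window, 60 dimensions at 4 channels, spanning 60 ms at 250 Hz) and a
   K-state hidden Markov model with full multivariate-Gaussian emissions is
   fit by exact Baum–Welch EM (compiled forward–backward/Viterbi core). A
   state's embedded covariance encodes band-specific power *and* lagged
   cross-channel structure, i.e. coherence.
2. **State fingerprints.** Per 2-min window: static Welch spectra (2-s Hann
   segments, 50 % overlap, 0.5 Hz grid over 2–100 Hz) and state-resolved
   spectra by masking the raw signal with the binarized Viterbi path and
   applying a 7-taper Slepian multitaper estimator (NW = 4). PSDs are
   averaged within region, magnitude-squared coherence over the four
   STN × CTX pairs, and summarized over five canonical bands (delta-alpha
   2–10, low-beta 12–20, high-beta 20–35, low-gamma 40–70, high-gamma
   70–100 Hz): 15 static features, 15 K state-resolved.
3. **State dynamics.** Fractional occupancy, mean lifetime, inter-visit
   interval and switching rate per state and window.
4. **Symptom models.** Gaussian GLMs of each symptom score on the feature
   sets, with participant/hemisphere fixed effects, per-coefficient t-tests
   and Benjamini–Hochberg FDR at α = 0.01.

Patient recordings of this kind are access-restricted, so the package
includes a ground-truth generator: Markov-switching AR(2) resonator signals
with state-specific peaks and plantable inter-regional coherence, plus
linear symptom scores — every stage of the pipeline is validated against
known truth. See the vignette `vignettes/state-dynamics.Rmd` for the
modelling details and design decisions.

## Worked example

```r
library(lfpstates)

# simulate 4 sessions (2 participants x 2 hemispheres) of 20 min with
# 4 planted oscillatory states and symptom scores driven by occupancy
d   <- make_dataset(default_sim_config(seed = 1))
pre <- lapply(d$sessions, preprocess_session)

emb <- unlist(lapply(pre, embed_session, L = 7), recursive = FALSE)

# two-stage fit: search for the basin on the first 5 min of each session,
# then refine on the full 80 min
sub   <- lapply(emb, function(e) e$X[seq_len(75000 - 14), ])
m0    <- suppressWarnings(fit_hmm(sub, K = 4, seed = 1, n_restarts = 3,
                                  max_iter = 20, tol = 1e-5))
model <- fit_hmm(emb, K = 4, init = m0, max_iter = 20, tol = 1e-5)
model
#> hmm_model: K=4 states, D=60 dims, loglik -39546517.16 (converged)
#>   self-transition probabilities: 0.993, 0.993, 0.993, 0.993

# decode and compare with the planted path
paths <- lapply(pre, decode_session, model = model, L = 7)
perm  <- match_states(unlist(paths), unlist(lapply(d$paths, `[[`, "states")),
                      K = 4)
attr(perm, "agreement")
#> [1] 0.9771714
```

The self-transition probabilities near 0.993 recover the planted 1-s mean
dwell (1 − 1/250 = 0.996), and the decoded path agrees with the ground
truth on about 98 % of samples after resolving label switching. Temporal
metrics of a window then read, e.g.:

```r
compute_temporal_metrics(c(1, 1, 2, 2, 2, 1), fs = 250, K = 2)
#>   state  fo mean_lifetime_s mean_interval_s switching_rate_hz n_visits
#> 1     1 0.5           0.006           0.012          83.33333        2
#> 2     2 0.5           0.012              NA          41.66667        1
```

(fractional occupancy sums to one; a state visited once has no inter-visit
interval). GLM reports print in the field's style:

```r
set.seed(2026)
feats <- as.data.frame(matrix(rnorm(2000 * 15), 2000,
                              dimnames = list(NULL, sprintf("f%02d", 1:15))))
y <- synth_symptoms(feats, symptom_model_spec(weights = c(f03 = 3, f11 = -3),
                                              noise_sd = 1), seed = 1)
fit_symptom_glm(feats, y)
#> glm_report: n = 2000 windows, R^2 = 94.3%, alpha = 0.01 (BH-FDR over 15 tests)
#>   f03: t(1984) = 130.40, p < 0.001
#>   f11: t(1984) = -130.40, p < 0.001
```

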