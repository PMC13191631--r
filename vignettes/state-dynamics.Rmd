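---
title: "Latent oscillatory states in cortico-subthalamic recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent oscillatory states in cortico-subthalamic recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic sensing from deep-brain-stimulation implants yields weeks of
continuous local field potentials (LFPs) from the subthalamic nucleus (STN)
and motor cortex (CTX) of people with Parkinson's disease, alongside
wrist-worn wearable scores of bradykinesia, dyskinesia and tremor at 2-min
resolution. Motor symptoms are classically linked to beta-band (12-35 Hz)
STN power, but the cortico-subthalamic circuit switches between transient
network configurations — states — that mix local rhythms and inter-regional
coherence across bands. `lfpstates` models those states explicitly and asks
which state-resolved spectral and temporal features track symptom severity.

## The model

The 4-channel signal (two STN and two CTX bipolar contact pairs per
hemisphere, 250 Hz) is lifted by time-delay embedding: each sample is
replaced by the window of lags $-L..+L$ around it, channel-major. With
$L = 7$ this is a 15-point window spanning 60 ms, i.e. a 60-dimensional
observation vector. A $K$-state hidden Markov model with full
multivariate-Gaussian emissions is then fit to the embedded series. Because
an embedded observation contains the local signal history, a state's
covariance matrix encodes autocovariance (hence band-specific power) and
lagged cross-channel covariance (hence coherence): states are
spectral/connectivity fingerprints, not amplitude levels.

Estimation is exact Baum-Welch EM with scaled forward-backward recursions,
implemented in compiled code. We chose deterministic EM over stochastic
variational schemes because at this problem size it is exact, reproducible
for a fixed seed, and directly testable against exhaustive enumeration on
tiny instances. Each contiguous recording segment is an independent
sequence sharing parameters; sequences are never concatenated across gaps.
Means are initialized from randomly drawn data rows and covariances from
the pooled covariance; by default the best of several restarts (by final
log-likelihood) is kept. Covariances receive diagonal loading
$\epsilon\,\mathrm{tr}(\Sigma)/D$ with $\epsilon = 10^{-6}$ each M-step.
Decoding produces smoothed posteriors (forward-backward) and the exact MAP
path (Viterbi; backtrace ties break toward the lowest state index, a stable
documented convention). State labels are arbitrary; `match_states()`
resolves label switching exhaustively for $K \le 8$ by samplewise agreement
(paths) or covariance correlation (models).

No PCA/whitening is applied to the embedded space before fitting: the
analysis operates on the raw embedded covariance. A projection step is a
common variance-reduction device in this model family, but it changes what
the state covariances mean, so it is deliberately omitted here.

## Preprocessing and epoching

Per channel, amplitude is normalized by the 95th percentile of $|x|$ — a
robust gain equalization that preserves waveform shape and relative
spectra; the exact statistic is configurable because "percentile
normalization" admits variants. Signals are then band-passed 2-120 Hz with
a 4th-order Butterworth applied forward-backward (zero phase) per segment;
phase distortion would corrupt cross-region coherence, hence filtfilt.
Segments shorter than three filter lengths are dropped.

Wearable scores arrive per 2-min window, timestamped at the window end (the
score summarizes the preceding 2 min); bradykinesia is stored as positive
(higher = worse). A hemisphere's recording is paired with the contralateral
wrist. Windows fully inside one contiguous segment become epochs of exactly
$120 \times f_s$ samples; partial windows are excluded and logged.

Inclusion rules, applied in order: (1) sleep — runs of at least 2
consecutive windows with bradykinesia above 80 are prolonged immobility and
are removed. A single isolated window is exactly, not more than, 2 min
long, so "duration > 2 min" is read as at least two consecutive windows
(configurable via `min_run_windows`). (2) Analysis-specific: bradykinesia
models keep windows at or above the participant's 30th bradykinesia
percentile; dyskinesia models keep windows below it (on-medication
periods); tremor models keep windows with tremor score above zero. The
percentile is computed per participant on the post-sleep record — computing
it before sleep removal is the other defensible reading; we remove sleep
first so the threshold reflects wakeful variation only, and the choice is
config-exposed. Filtering is idempotent (a filtered dataset is returned
unchanged), and every excluded window carries a reason code so that kept +
excluded partition the input.

## Spectral characterization

Static, per-window spectra use Welch's method: 2-s Hann windows, 50%
overlap, giving a 0.5 Hz grid; analysis is restricted to 2-100 Hz.
Magnitude-squared coherence is formed from auto- and cross-spectra pooled
over the window's segments, then averaged over the four STN x CTX channel
pairs; PSDs are averaged within region (the bipolar pairs at each site
overlap spatially).

State-resolved spectra follow the masking construction: the raw
(non-embedded) signal is multiplied element-wise by the binarized Viterbi
time course of a state, and the masked signal is analysed with a Slepian
multitaper estimator — 7 tapers, time-bandwidth product NW = 4, 2-s
windows, 50% overlap. The 2-s window length follows from the stated 0.5 Hz
resolution; with NW = 4 the bandwidth is 4 Hz and $2NW-1 = 7$ tapers is
the standard choice. Masking biases absolute power downward in proportion
to fractional occupancy and smears spectra at state edges; all downstream
use is comparative (within-feature regression), so this bias cancels in
effect directions, and states below a 2-s minimum occupancy per window are
treated as missing rather than zero. The Slepian tapers are computed from
the symmetric tridiagonal eigenproblem, so no special-function libraries
are involved.

Band features average each region-metric (STN PSD, CTX PSD, STN-CTX
coherence) over five canonical bands — delta-alpha 2-10, low-beta 12-20,
high-beta 20-35, low-gamma 40-70, high-gamma 70-100 Hz (edges inclusive;
the 10-12 and 35-40 Hz gaps are intentional). That is 15 features static,
15K state-resolved (60 at K = 4). Arithmetic means of raw power are used;
a log-transform option exists in the band-feature layer but averaging raw
power is the default.

## Temporal metrics

From the per-window Viterbi path: fractional occupancy (FO; sums to one
across states), mean lifetime of visits, mean inter-visit interval, and a
per-state switching rate (visits per second; a global label-changes-per-
second variant is also provided since "switching rate" admits both
readings). Edge-truncated runs count as visits — excluding them would
systematically discard long dwells; a config flag allows the stricter
variant. Absent states yield missing values, never zeros, and are dropped
from that state's temporal model rather than imputed.

## Symptom models

All three model families are Gaussian-identity GLMs (ordinary least
squares) — the response is a continuous score and the reported statistics
are coefficient t-tests and $R^2$, which pins the family. Participant and
hemisphere enter as dummy-coded fixed-effect covariates; predictors of
interest are z-scored so coefficients are comparable; the response stays on
its native scale. Per family: static (15 features), state-resolved (15K
features; windows missing any state dropped complete-case), temporal (one
model per state x metric, single predictor plus covariates). FDR is
Benjamini-Hochberg at $\alpha = 0.01$; the family is the within-model
predictor set for the spectral models and the full state x metric set for
the temporal models (the narrower and wider readings respectively of an
under-specified correction scope; both are configurable). Positive t means
the feature predicts a worse score.

## The synthetic-data generator

Real patient recordings of this kind cannot be redistributed, so the
package ships a generator that emulates the statistical structure the
analysis assumes, with full ground truth: a Markov chain switches at sample
resolution between K states (geometric dwell; abrupt switches, matching the
HMM's own assumption — no cross-fades), and each state contributes
stochastically driven damped resonators (AR(2), pole radius set from the
requested bandwidth) plus white measurement noise. Oscillators flagged
coherent share one driving process across channels, planting inter-regional
coherence at their centre frequency; others are independent per channel.
Resonators run continuously and are gated by the state indicator, so
within-state spectra are stationary. Pure sinusoids are deliberately
avoided: HMMs on tones are degenerate, and real LFP rhythms have width.

The default configuration is the package's reference validation surface:
four states at 250 Hz with mean dwell 1 s, four sessions (2 participants x
2 hemispheres) of 20 min each, and fingerprints chosen to span the
phenomenology of this circuit — uncoupled STN (24 Hz) and CTX (18 Hz) beta
(state 1); coherent high-beta at 27 Hz plus STN low-gamma at 55 Hz (state
2); STN gamma at 65 Hz with broad delta/alpha (state 3); STN low-beta at
15 Hz plus coherent high-gamma at 80 Hz (state 4). Oscillator standard
deviations are of the order of the noise floor (gains 0.5-1.2 against unit
noise), giving clear but not caricatured spectral peaks. Symptom scores are
linear in true per-window state occupancies plus participant/hemisphere
offsets and Gaussian noise, at exact 2-min boundaries aligned to the signal
start (no clock drift); tremor is truncated at zero, mimicking a wearable
that reports zero when no tremor is detected. No phase-amplitude coupling
is planted: the state definitions here are second-order (power and
coherence), and the generator emulates exactly what the model class can
express.

What passing on this generator does and does not show: it demonstrates
that the estimation chain recovers planted states, spectra, dynamics and
regression structure when the data match the model's assumptions. Real
recordings add nonstationary artifacts, line noise, 1/f background,
medication cycles and annotation jitter that the generator intentionally
omits; results on real data depend on those, and the package's filters
address only the documented exclusion rules.

## Numerical choices and problem sizes

EM stops when the relative log-likelihood change falls below `tol`
(default 1e-6; the validation runs use 1e-5) or at `max_iter`;
non-convergence returns the model with a flag and warning rather than
failing. The log-likelihood is non-decreasing per iteration up to 1e-8
relative tolerance, and this is asserted in the test suite. Degenerate
inputs fail loudly: flat channels, non-stochastic transition rows,
rank-deficient designs and out-of-range states all raise errors naming the
offender.

The validation suite exercises the full chain at the reference scale (four
20-min sessions, 1.2 million embedded observations of dimension 60) and
verifies decoding accuracy and planted-peak recovery there. The fit is
two-stage: a multi-restart basin search on the first five minutes of each
session, then warm-started EM on the full data (`fit_hmm(init = )`). At
this scale single-restart EM from random data rows can land in a poor
local optimum; the cheap subsample stage reliably finds the right basin
first.
GLM power and false-discovery calibration use 2,000-window and 200 x
500-window feature-level simulations. These sizes are the package's
validation choices: large enough for the asymptotics each check relies on,
small enough to run routinely.

A note on model-order selection. `compare_k()` reports BIC, but on
oscillatory signals BIC systematically over-selects K for this model
family: the HMM treats embedded observations as conditionally independent
given the state, while a resonator's samples are autocorrelated within a
state, so additional states can track oscillator phase and buy likelihood
far in excess of the BIC penalty. We verified this on the package's own
generator across gain/bandwidth regimes (K = 6 beats K = 4 by thousands of
nats on 4-state data). BIC's consistency holds when the data come from the
model class itself — state-conditional Gaussian emissions — and that is the
setting in which the suite validates order recovery (it succeeds there
when EM has enough restarts to avoid local optima; a reduced 6-dimensional
configuration keeps the 20-seed x 3-K sweep affordable). This is exactly
why `compare_k` returns a diagnostic table — likelihood, BIC, and the
spectral band contrast between states — for a human choice, rather than
auto-selecting: for real recordings, state-spectra clarity, not an
information criterion, is the operative selection principle.

## Known limitations

- The HMM assumes geometric dwell times; strongly non-geometric state
  durations would need a duration-explicit model, which is out of scope.
- Masked multitaper spectra are biased by occupancy (see above); a
  segment-wise estimator on within-state runs would trade bias for
  variance and is not the default.
- Fixed-effect covariates absorb between-participant offsets but not
  participant-specific slopes; mixed models are intentionally not used.
- The delimited-text reader expects the package's own header convention;
  proprietary device telemetry formats are not parsed.
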