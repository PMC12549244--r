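---
title: "Modeling operator trust from multimodal physiology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling operator trust from multimodal physiology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trustdyn)
```

## The problem

In human-autonomy teaming, a supervisory operator's *trust* in an autonomous
teammate fluctuates on the scale of minutes as the system succeeds, errs, and
explains itself. trustdyn implements a pipeline that estimates a continuous
trust report (a visual-analog slider value in $[0,1]$, collected every 45 s)
from six concurrent physiological streams — ECG, electrodermal activity
(EDA), respiration, 19-channel EEG, 20-channel fNIRS, eye tracking — plus
logged task-interaction ("embedded") measures and stable operator background
variables.

The statistical core is an ordinary least squares model
$y = \beta_0 + \beta_1 X_1 + \dots + \beta_p X_p$ whose predictors are
chosen from ~1,800 candidates by two-round relaxed-LASSO stability
selection, validated externally with grouped Monte-Carlo cross-validation
that withholds whole trials.

Because no human-subject data ship with the package, a synthetic study
generator reproduces the protocol — 12 participants x 4 sessions x 6 trials
x 8 epochs of 45 s, a 2-min pre-experimental rest baseline per session and
45-s pre-trial baselines, four autonomous-system conditions crossing
reliability (67% / 84%) with explainability (low / high) — and plants a
known sparse linear trust structure so that every pipeline stage is testable
against ground truth.

## The synthetic study

### Latent structure

Per epoch, standard-normal latent scores $z$ drive 15 generator parameters
spanning all six streams (mean heart rate and R-R variability, tonic skin
conductance level and slope, SCR amplitude, breathing rate and depth,
alpha/theta band power on Pz/Fz/O1, fNIRS response amplitude on two
channels, pupil diameter, blink rate, fixation duration). The latents share
a common arousal-like factor: pairwise correlation
`latent_correlation = 0.25` by default, reflecting that autonomic and
attentional indices co-vary in real operators. Trust is

$$y = \mathrm{clip}\left(\beta_0 + c_s + u_p + \textstyle\sum_j \beta_j z_j
+ \varepsilon,\ 0,\ 1\right)$$

with $\beta_0 = 0.55$, a session condition shift $c_s$ (+0.05 for
high reliability, +0.03 for high explainability, centered), a participant
shift $u_p$ (SD 0.06, 60% of it carried by the dispositional
propensity-to-trust background score), equal positive coefficients scaled
so the planted linear term has SD 0.17 (each link's physiological
direction lives in the latent-to-parameter maps), and noise $\varepsilon$
sized so the planted term explains 85% of the pre-clipping variance.
Under equicorrelation $\rho$ each latent's *marginal* standardized effect
is $\sqrt{0.85/15}\,\sqrt{1 + 14\rho} \approx 0.5$ SD at the default —
individually strong readouts — while the *unique* per-latent contribution
stays sparse, which is exactly the regime stability selection is built
for.

All latent-to-parameter links are monotone (log-linear for rates and
powers, linear for levels), so the corresponding extracted feature is a
noisy monotone readout of its latent.

### Signal physics

* **ECG** — P-QRS-T complexes placed at truncated-normal R-R intervals,
  plus baseline wander, a 60 Hz mains component, and broadband noise.
* **EDA** — a tonic level with slow drift plus Bateman-shaped skin
  conductance responses ($\tau_r = 0.75$ s, $\tau_d = 2$ s, unit-peak
  scaled) at Poisson times. Within a trial the tonic path is continuous
  (piecewise-linear through two anchors per epoch that encode the epoch's
  planted level and slope): a level step at an epoch boundary would
  deconvolve into a spurious SCR-like driver spike, which is a generator
  artifact no real skin produces.
* **Respiration** — cycle-by-cycle oscillation with configurable inhale
  fraction and 5% cycle-duration variability.
* **EEG** — per channel, band-structured Gaussian noise synthesized in the
  frequency domain under 4th-order-Butterworth magnitude envelopes for the
  five canonical bands (delta 30, theta 15, alpha 20, beta 8, gamma 3
  uV^2 by default), plus shared blink transients (~80 uV, 0.35 s) weighted
  toward the frontal 10-20 electrodes.
* **fNIRS** — gamma-kernel hemodynamic responses (time-to-peak 6 s, with a
  25% undershoot) at 4 events/min per channel — matching the task's two
  stimuli per 30 s — plus linear drift, ~1.1 Hz cardiac ripple, and noise;
  HbR mirrors HbO at -0.4 amplitude.
* **Eye tracking** — a pupil series (slow wander, 0.2 Hz hippus, blink
  dips) and alternating fixation/saccade event lists over four screen
  areas of interest.

Embedded measures follow monotone behavioral links from the operator's
*noise-free* trust state (behavior reflects internal trust, not the
slider's report noise): a trusting operator reviews fewer classifications,
agrees — often passively — more, decides faster, and spends more effort on
the map task. The behavioral noise scale (0.45 on the latent propensities)
puts each measure at roughly $r \approx 0.2$–$0.3$ with trust: strong
enough to be retained by selection, weak enough that the behavioral block
does not collectively screen off the physiological signal. An early
version of the generator drove behavior from the post-noise report with
much less noise; the embedded block then predicted trust better than the
true latents and selection ignored physiology entirely — a useful reminder
that simulated "behavioral" channels sit causally downstream of the target
and must be noised accordingly.

What the generator does **not** emulate: motion artifacts other than EDA
range violations and EEG blinks, electrode drift or detachment,
inter-stream latent correlation (each planted latent is independent),
autocorrelated trust dynamics within a trial, or learning effects across
sessions. Tests passing on this generator therefore demonstrate pipeline
correctness and statistical behavior under a known model — not performance
on real operators.

Raw waveforms are never stored: every trial and baseline window has a named
child seed, and `epoch_signals()` / `baseline_signals()` regenerate the
bundles deterministically, which keeps datasets small (delimited tables +
a JSON manifest) and memory flat during extraction.

## Preprocessing

All filters are 4th-order Butterworth applied forward-backward
(`signal::filtfilt`), hence zero-phase; filtering is per *trial*
(continuous recording) and the result is sliced into epochs, avoiding edge
transients at epoch boundaries.

* ECG: 1 Hz highpass, 100 Hz lowpass, 59-61 Hz bandstop; R-peaks by a
  threshold detector (half of the 99.9th percentile) with local-maximum
  refinement and a 200 ms refractory period; flat or peak-free input yields
  an empty list plus a quality flag rather than an error.
* EDA: samples outside 1-40 uS replaced by linear interpolation (a gapless
  series is required downstream), 3rd-order Savitzky-Golay smoothing,
  resampling to 10 Hz. More than 50% out-of-range flags the epoch unusable.
* EDA decomposition: the discrete Bateman kernel is the impulse response of
  an ARMA(2,1) system, so deconvolution is an exact 3-tap inverse filter.
  The raw driver is split into a smooth tonic floor (4-s running median,
  Savitzky-Golay smoothed — SCR impulses are brief and sparse, so the
  windowed median tracks the tonic-driven baseline) and a non-negative
  phasic driver (3-sample smoothing, 4 x MAD noise gate). The phasic
  component is the driver re-convolved with the kernel; the tonic component
  is the remainder, so reconstruction is exact by construction. SCR events
  are driver pulses whose peak contribution exceeds 0.01 uS.
* Respiration: 0.05-3 Hz band-pass (preserving 3-180 breaths/min — the
  stated intent of the cleaning protocol, implemented as a band-*pass*),
  breath cycles from upward zero crossings with a 1/3-s minimum spacing.
* EEG: 0.5-55 Hz bandpass, then FastICA (symmetric fixed-point, tanh
  contrast, unmixing estimated on a <=6,000-sample temporal subsample and
  applied to the full trial). Components are rejected automatically when
  sample kurtosis exceeds 5 *and* more than half the absolute mixing
  weight sits on the seven frontal electrodes — a reproducible stand-in
  for manual ocular-component rejection. Non-convergence of the symmetric
  iteration is expected when most sources are near-Gaussian (their
  rotation is unidentifiable) and is not treated as failure; the
  non-Gaussian ocular directions are still isolated.
* fNIRS: 0.016-0.5 Hz bandpass per channel on HbO and HbR independently.

## Features, versions, imputation

The dictionary is frozen at 682 base features: ECG 28, EDA 63, respiration
28, EEG 125 (19 channels x 5 bands + 6 regional means; gamma is integrated
over 30-55 Hz because the chain lowpasses at 55 Hz), fNIRS 360 (18 per
channel), eye 37, embedded 16, background 25. The psychophysiological
blocks (ECG, EDA, respiration, eye: 156 features) receive all eight
baseline versions — differences and ratios against the per-trial pre-trial
baseline, the session-mean pre-trial baseline, and the pre-experimental
baseline, plus participant standardization and centering — while EEG
receives only the per-trial ratio (v4) and fNIRS only the per-trial
difference (v1), the conventional normalizations in those fields. The
expansion is $156 \times 8 + 125 + 360 + 16 + 25 = 1774$ predictors. (The
creation counts per category sum to 682; a commonly quoted total of 680
for this feature set does not match its own per-category sums, and the
dictionary follows the per-category counts.)

Interpretations fixed here: trial 1 has no separate pre-trial baseline and
uses the last 45 s of the pre-experimental rest; the "mean pre-trial
baseline" is the within-session mean; participant statistics for v7/v8 are
computed from *training* epochs only and applied to test epochs, because a
naive all-data mean leaks the test partition into the predictors. A value
equal to its baseline yields ratio 1 (this also covers the 0/0 of features
that are constant by construction, such as the phasic-driver minimum);
other zero denominators, and v7 of a constant series, are flagged missing.

Missing cells are imputed from the closest level of the protocol
hierarchy: the trial's other epochs, then the session's other
observations, then the participant's other sessions — never across
participants at these levels, and observed values are never modified. Two
documented extensions keep the default pipeline total: a version that is
degenerate for an entire participant (e.g. the participant-standardized
version of a series constant for that participant — common for quantized
features such as the dominant breathing frequency) falls back to the
cross-participant column mean, and a column observed nowhere becomes the
inert constant 0; both are recorded as provenance level 4, and
`population_fallback = FALSE` restores the strict within-participant
contract.

## Model building

Selection runs in two rounds on the training partition. Round 1: 50
repetitions (default) of 10-fold cross-validated LASSO (`glmnet`, internal
standardization, 100-point log-spaced lambda grid) with re-randomized
folds, recording the support at both the 1-SE and the minimum-MSE lambda —
up to 100 sets, unique sets retained. Round 2 offers the *union* of all
round-1 features (the union, not the intersection, because intersections
empty out under stochastic folds) to 50 further repetitions at the 1-SE
rule. Each round-2 set is refit by OLS (exactly collinear columns dropped
with a warning — versions of one feature can coincide numerically), scored
by adjusted $R^2$ and by exhaustive leave-one-trial-out $Q^2$
($1 - \mathrm{PRESS}/\mathrm{TSS}$ with the training-partition mean, each
held-out trial predicted with capping to $[0,1]$, consistent with the
capping rule's placement).

Two anti-overfitting constraints then eliminate candidates: the predictor
count may not exceed 1/5 of the training observations, and
$|R^2_{adj} - Q^2|$ may not exceed 0.2. Among survivors the highest
adjusted $R^2$ wins ("highest R^2" is read as adjusted $R^2$, the
per-model quantity this pipeline computes); ties break toward fewer
predictors, then lexicographic predictor order, for determinism. If every
candidate is eliminated the error says so explicitly — the constraints are
never relaxed silently. Both fractions are exposed as arguments because
the 1/5 cap is calibrated to the full-scale study (1,920 training
epochs): under the synthetic conditions at strongly reduced problem sizes
the 1-SE sets are stable, well-validated ($|R^2_{adj} - Q^2| \approx
0.03$) and sit at $p/n \approx 0.22$, so the reduced-scale test and
acceptance runs state `max_p_fraction = 1/3` explicitly.

Predictions are capped to $[0,1]$; the uncapped value and a capped-count
are kept for diagnostics. Test metrics are RMSE, **median** absolute error
(MAE here is the median, not the mean — an easy misreading, asserted by a
dedicated test), and test $Q^2$ against the training mean.

External validation is leave-one-trial-out-per-session Monte-Carlo
cross-validation: per split, one uniformly random trial per
participant-session is withheld (1/6 of epochs under the default design),
the whole selection pipeline reruns on the training partition (including
v7/v8 statistics and imputation), and the selected model is scored on the
withheld trials; ten splits by default, with mean and SD rows, a
per-participant RMSE table and stored predictions for one designated
split. The all-data descriptive model reuses the same pipeline on 100% of
the epochs and reports per-category predictor retention.

## Problem sizes used by the shipped checks

The test suite and acceptance script choose sizes that keep a full run in
the tens of minutes on one CPU while preserving the protocol's structure:

* unit fixtures: 2 x 2 x 3 x 4 epochs at reduced sampling rates (ECG 250,
  EEG 125, pupil 60 Hz);
* support-recovery checks: five independent studies of 4 participants x 2
  sessions x 6 trials x 8 epochs at reduced rates, EEG ICA disabled, 3+3
  selection repetitions, 40-point lambda grid, cap n/3;
* the acceptance script: structural counts from the full 12 x 4 x 6 x 8
  protocol, and an end-to-end run (extraction at default rates, ICA on) at
  3 participants x 4 sessions x 6 trials x 8 epochs with 2 Monte-Carlo
  splits and the same reduced selection configuration.

Sampling rates, repetition counts, split counts and the cap fraction are
the only quantities scaled down; epoch duration, baseline structure,
feature dictionary, versioning, imputation, selection rules and metrics
are identical to the full-scale configuration.

## Known limitations

* Latents are i.i.d. across *epochs* (no within-trial autocorrelation),
  and the cross-feature correlation is a single equicorrelated factor —
  both simpler than real physiology; the generator's event-count noise
  (Poisson SCRs and blinks) still makes some planted features genuinely
  hard to recover, which is intended.
* Because a planted latent modulates a signal *property*, many features of
  its stream are valid readouts (a heart-rate shift moves every R-R level
  statistic); support recovery is therefore scored at the latent level via
  `planted_trace_features()` — a model that captures the latent through a
  sibling feature (e.g. `ecg_rr_min` instead of `ecg_rr_mean`) has
  recovered it.
* The Ledalab-style decomposition is an exact-deconvolution reimplementation,
  not a port; SCR onset timing is biased ~1 s early by the driver
  smoothing, which cancels in baselined feature versions but matters if
  absolute latencies are of interest.
* FastICA with near-Gaussian sources removes the ocular subspace reliably
  but the retained "components" are not uniquely identified; only the
  reconstruction, not the component ordering, is contractual.
* Imputation level 4 (cross-participant fallback) departs from the strict
  within-participant hierarchy; it touches only columns a participant
  cannot support and is recorded per cell in the provenance mask.
* At desk-scale sample sizes the 1/5 predictor cap interacts with the
  synthetic signal breadth (see above); conclusions about the cap itself
  should come from full-scale runs.
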