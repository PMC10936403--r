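---
title: "Quantifying the five times sit-to-stand test from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the five times sit-to-stand test from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitstand)
```

## The problem

The five times sit-to-stand test (FTSS) — stand up and sit down five times
as quickly as possible — is a routine clinical measure of lower-limb
strength, endurance and falls risk in older adults. A single inertial
measurement unit (IMU) worn on the sternum or the lateral thigh records the
movement as tri-axial acceleration and angular velocity, and from that
recording one can quantify not just the total test time a stopwatch would
give, but the timing, variability, postural sway, smoothness and spectral
complexity of every individual sit-stand-sit (SSS) cycle. Those signal
features in turn carry information about balance (Berg Balance Scale, BBS,
0–56), cognition (Mini-Mental State Examination, MMSE, 0–30) and
retrospective falls history.

`sitstand` implements that entire chain: signal conditioning, adaptive
phase segmentation, a frozen feature roster, intra-session reliability,
exploratory statistics, and two cross-validated estimation pipelines
(logistic classification with sequential forward selection; elastic-net
penalised Poisson regression). Because clinical FTSS datasets are rarely
shareable, the package also contains a first-class synthetic generator that
produces IMU recordings with known fiducial times and cohorts with known
outcome-generating models, so every stage can be validated end to end.

## Signal conditioning

Recordings are nominally sampled at 102.4 Hz. The fixed processing order is
**calibrate → band-pass filter → trim**, asserted at run time:

* **Calibration** follows the standard sensor model
  `corrected = A (raw − offset)`, applied independently to the
  accelerometer and gyroscope triads. The neutral calibration is the
  identity.
* **Filtering** uses a 2nd-order Butterworth band-pass, 0.01–5 Hz, applied
  forward and backward (`signal::filtfilt`), giving an effective 4th-order
  zero-phase response. Zero phase matters: a causal filter would delay
  every fiducial time by a frequency-dependent lag. The band edges follow
  standard practice for sit-to-stand accelerometry — DC (gravity) is
  rejected exactly, movement content up to 5 Hz is preserved (gain ≥ 0.95
  at 1 Hz, ≤ 0.1 at 20 Hz).

  One numerical subtlety: the 0.01 Hz pole has a time constant
  (≈ 16 s) comparable to a whole trial, so a two-pass filter started from
  zero initial conditions produces a start-up transient that tilts the
  baseline across the entire recording and modulates trough depths by as
  much as a quarter of their amplitude. `bandpass_filter()` therefore
  mirror-pads each channel by three time constants before filtering and
  discards the padding afterwards — the same edge handling that mature
  signal-processing environments build into their `filtfilt`.
* **Trimming** removes the first second of each trial (sensor settling) and
  re-references time to zero; the removed offset is reported so fiducials
  can be mapped back to the raw time base.

Validity gates run on the *unfiltered* data, where artifacts are still
sharp: a spike check (samples beyond 10 trial standard deviations of the
trial median — an absolute-deviation rule tied to the noise floor would
flag every genuine stand pulse, because most of a trial is quiet sitting),
a dropout check (inter-sample gaps above 3 nominal intervals), and an
orientation check. Whole-trial skewness turns out to be too weak to gate
orientation on — the two positive pulses and one negative trough per cycle
nearly cancel the third moment (≈ +0.08 on clean torso trials) — so the
check uses the morphological fingerprint instead: a correctly mounted torso
sensor shows at least as many supra-threshold positive peaks as negative
troughs (two stand/sit pulses per mid-stand), and a thigh sensor's extremes
must be dominated by the negative mid-stand trough. Skewness is still
reported as a diagnostic.

## Segmentation

Both detectors are *adaptive*: every threshold is a fraction of the trial's
own signal extremes, which makes detection invariant to positive rescaling
of the trace (sensor gain, subject vigor).

**Torso.** Positive peaks of the Z-axis (anteroposterior) acceleration
exceeding `0.4 · max(az)` mark stand-start and sit-end; negative peaks
below `0.5 · min(az)` mark mid-stand. Candidate peaks are every local
extremum beyond the threshold (a supra-threshold region may hold two
distinct peaks — a sit-end and the following stand-start — separated by a
shallow valley), refined to the nearest local extremum when a region is
clipped by the signal edge (the step-back search). Same-sign peaks closer
than a 0.5 s refractory period are merged, keeping the more extreme —
a physiological lower bound on SSS phase duration. Alternation is then
enforced: each accepted mid-stand is the most negative peak between a pair
of adjacent positive peaks; the preceding positive peak is its stand-start,
the following one its sit-end. Candidate cycles shorter than 1 s are
discarded as sub-physiological (this also removes spurious cycles that
noise can assemble inside the seated pauses between true cycles).

**Thigh.** The femoral (Y-axis) acceleration is dominated by a sustained
negative excursion while the subject is off the chair, deepest at
mid-stand. The trial minimum defines the acceptance rule: local minima
below `0.8 · min(ay)` are successful SSS attempts; shallower dips — e.g. an
aborted half-rise — are rejected by design. Stand-start and sit-end are
located as movement onset/offset: the nearest samples before/after each
mid-stand where the deviation from the *seated baseline* falls below 10% of
the trough depth. The baseline is estimated from the first half second of
the (trimmed) trial, because after band-pass filtering the DC level is
arbitrary and "near zero" is meaningless; the protocol guarantees a seated
start.

Both detectors run on a lightly smoothed copy of the channel (0.25 s
zero-phase moving average). The SSS pulses are several times wider than
the smoothing window, so their amplitudes shrink only slightly and
uniformly, while high-frequency noise — which would otherwise inflate the
trial extremes that the adaptive thresholds hang off — is attenuated.
Symmetric smoothing leaves peak timing unbiased.

## The feature roster

`extract_features()` assembles a frozen, ordered roster
(`roster_version = "reconstructed-v1"`): 38 features for the torso, 20 for
the thigh.

| family | torso | thigh |
|---|---|---|
| timing: total time, cycle count, mean/SD/CoV of SSS, rise, descent durations | 11 | 11 |
| amplitudes at fiducials (primary accel + pitch gyro; mean and SD across cycles) | 12 | 8 |
| per-axis RMS of acceleration and angular velocity (postural sway) | 6 | — |
| per-axis RMS of jerk and angular acceleration (smoothness) | 6 | — |
| normalized spectral entropy (complexity) | 3 | 1 |

Sway and jerk are torso-only: a thigh-mounted sensor cannot meaningfully
measure upper-body sway. Thigh amplitude features use stand-start and
mid-stand only, where its morphology is informative. All sway, jerk and
entropy features are computed over the task window (first stand-start to
last sit-end), excluding quiet sitting, since sway *during the task* is the
target. Derivatives are central differences at the sampling rate. Spectral
entropy is the Shannon entropy of the normalized one-sided periodogram (DC
excluded) divided by `log(#bins)`, so a pure tone scores near 0 and white
noise near 1; it is computed per acceleration axis (torso) or on the
femoral channel (thigh) — the windowing and per-axis choice were left open
by the source method and fixed here. The pitch gyroscope axis is chosen
per trial as the axis of maximal variance in the task window, robust to
mounting variation.

## Reliability and exploratory statistics

`icc_2k()` implements the two-way random-effects, absolute-agreement,
average-of-k intraclass correlation from the ANOVA mean squares,

$$\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

with a Shrout–Fleiss F-based 95% interval (single-rater bounds stepped up
by Spearman–Brown; a bound at or below the step-up pole is reported as −1).
Absolute agreement was chosen over consistency — the source method did not
state which — because repeated trials within a session share no calibration
that would justify ignoring trial-level offsets. Bands use the
conventional cut-points, strictly: > 0.9 excellent, > 0.75 good, 0.5–0.75
moderate, < 0.5 poor.

`association_tests()` averages features per subject across trials *before*
testing (Spearman vs. MMSE and BBS; Wilcoxon rank-sum fallers vs.
non-fallers; chi-square for categorical study-arm contrasts), mirroring the
exploratory analysis conventions of the field. No multiplicity correction
is applied, deliberately. Fallers are subjects with more than one fall in
the previous 12 months or any injurious fall; impairment labels use
MMSE < 27 and BBS < 53.

## The two estimation pipelines

Both pipelines model one row per subject (first trial only) with the
roster features plus age, sex, height and weight, and both are *forced* to
include the total test time — the one feature a stopwatch already gives —
so the models answer "what do the sensors add?".

**Classification** (`sfs_logistic_cv()`): stratified 10-fold outer CV; in
each fold, sequential forward selection grows the model greedily from the
forced set, scoring candidates by 5-fold inner cross-validated accuracy on
the training subjects only, and stops when the best addition improves by
less than 0.5 percentage points. A maximum-likelihood logistic fit on the
selected features predicts held-out subjects at threshold 0.5 (no
operating-point tuning), and outer-fold predictions are pooled into one
confusion matrix. Standardization parameters are learned on training rows
only. Quasi-separated fits fall back to a tiny-ridge (1e-6) IRLS that
keeps coefficients finite. The inner criterion, stopping rule and
threshold were open choices; they follow the standard nested-CV scheme
whose defining property — held-out subjects cannot influence their own
fold's selection — is asserted by a dedicated test and by a chance-level
(permuted-label) experiment.

**Regression** (`poisson_elastic_net_cv()`): the scores are bounded counts,
modeled with a Poisson log link. The elastic-net mixing parameter is 0.1 a
priori (mostly ridge, enough lasso for sparsity). Within each outer fold
the penalty strength is chosen by inner cross-validated deviance *subject
to* the active set holding 3–20 features; if no path solution satisfies the
bounds the nearest-size solution is used with a warning. The forced
feature is excluded from the penalty — the only mechanism that guarantees
its inclusion. Metrics (R², RMSE, Spearman ρ) are computed on pooled
held-out predictions; model size is the median across folds.

## The synthetic generator

`simulate_ftss_recording()` builds the primary channel from scheduled cycle
events: per cycle a positive Gaussian-windowed half-cosine pulse at
stand-start, a negative trough at mid-stand and a positive pulse at sit-end
(torso), or a shallow sustained plateau spanning the cycle plus a dominant
mid-stand trough (thigh). Pulses are smooth and effectively band-limited
within the analysis band. The pitch gyroscope channel is a scaled
derivative of the primary channel; remaining channels carry low-amplitude
sway. Defaults are the study conditions: 5 cycles of 2.4 ± 0.25 s (clipped
to 1.5–3.5 s), rise fraction 0.45, torso peaks 2.0 m/s² and troughs
−1.6 m/s², thigh minima −3.0 m/s², seated pauses of 0.8 ± 0.1 s, 2 s of
quiet sitting on either end, additive sway noise of 0.05 m/s² RMS
band-limited to 0.1–2.5 Hz (the postural-sway band), and per-event
amplitude jitter of 1.5% SD clipped at ±2 SD. Two of these deserve
comment:

* the seated pause exceeds the detector's 0.5 s same-sign refractory, so
  adjacent sit-end/stand-start pulses are resolvable — shorter pauses merge
  them into a single peak by construction, for any detector with a
  physiological refractory;
* amplitude jitter is small because the thigh acceptance rule *defines*
  successful attempts as those within 80% of the deepest trough; a
  generator emulating successful cycles must respect the band that defines
  them. Failed attempts are modeled explicitly as `aborted_rise`
  artifacts instead (plus `spike` and `dropout` artifact types).

`simulate_cohort()` draws subject-level kinematics (mean cycle duration,
rise fraction, movement amplitude), then generates MMSE and BBS as Poisson
draws (clipped at the scale ceilings 30 and 56) from log-linear predictors
on the z-scored kinematic truth, and faller status from a logistic
predictor; falls histories are generated consistently with the faller
definition. All coefficients are recorded, so downstream models can be
checked against the generating process.

**What passing tests do and do not show.** The generator reproduces the
morphology the detectors rely on, with stationary noise and near-constant
successful-attempt amplitudes. Real recordings add gravity reorientation
during trunk pitch, inter-cycle fatigue drift, heterogeneous artifact
shapes and genuinely shallow successful attempts. Green tests therefore
demonstrate internal correctness (detectors recover what the model of the
signal says is there; pipelines recover known coefficients without
leakage), not clinical validity on real cohorts.

## Numerical choices and degenerate inputs

* Irregular timestamps within ±5% of the nominal interval are accepted
  without resampling; beyond that the recording is rejected — resampling
  would be silent data invention.
* CoV guards against division by a near-zero mean (error, never NaN);
  constant features in association tests report `NA` with a note; zero
  denominators in classification metrics report `NA`.
* Ties in peak refinement break to the earliest sample; flat-top peaks
  take their first sample.
* Fold assignment is a pure function of (n, seed, strata) and restores the
  global RNG state, so every run is reproducible from its configuration.
* Perfect-agreement ICC matrices short-circuit to ICC = 1 with a degenerate
  interval rather than dividing by zero.

## Measured robustness and limitations

On 100 clean simulated trials per sensor (3–8 cycles, durations 1.8–3.0 s),
cycle-count recovery is 100% for both detectors and the median absolute
fiducial timing error is below 0.02 s. Under increasing sway noise the
torso detector holds ≥ 95% recovery up to roughly 15% of its pulse
amplitude and degrades beyond; the thigh detector is intrinsically less
tolerant, because its 0.8-of-minimum acceptance band is only ~20% of the
trough depth wide — once noise spreads trough depths across that band, the
rule (correctly, by its own definition) rejects shallow-looking cycles.
This is a property of the published thresholds, not of the implementation;
the property suite asserts the levels the thresholds genuinely support.

With the default (deliberately moderate) outcome coefficients, the
simulated 168-subject cohort yields balance-classification accuracy in the
low 60s and a BBS Spearman ρ ≈ 0.4, while MMSE — given a weak true effect —
is essentially unpredictable; reliability is bimodal (mean-based features
near ICC 1, dispersion-based features near 0) because within-subject trial
variation is purely stochastic in the generator. Real cohorts show
intermediate reliability and stronger demographic confounding. Problem
sizes used throughout the test suite and acceptance script (100 trials per
sensor, 20 permutation repeats at n = 168, elastic-net recovery at
n = 1000, one full 168-subject pipeline run twice) were chosen to estimate
each property stably on a single CPU.
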