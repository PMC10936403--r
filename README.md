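# sitstand

Quantifying the five times sit-to-stand test (FTSS) from a single
torso- or thigh-mounted inertial sensor.

The FTSS — stand up and sit down five times as quickly as possible — is a
standard clinical test of lower-limb strength, endurance and falls risk in
older adults. Instrumenting it with a body-worn IMU (tri-axial
accelerometer + gyroscope, nominally 102.4 Hz) turns a single stopwatch
number into a rich movement record. `sitstand` provides the full analysis
chain:

* **Signal conditioning** — Ferraris-style calibration, zero-phase
  2nd-order Butterworth band-pass (0.01–5 Hz, applied forward-backward),
  settling-time trimming, and validity gates (spikes, dropouts, sensor
  orientation).
* **Segmentation** — adaptive peak detection of every sit-stand-sit (SSS)
  cycle's *stand-start*, *mid-stand* and *sit-end* fiducial times. Torso:
  positive Z-axis peaks above 0.4·α<sub>z-max</sub> and negative peaks
  below 0.5·α<sub>z-min</sub>, with alternation enforcement and a
  step-back search to local extrema. Thigh: femoral-axis minima below
  0.8·α<sub>y-min</sub> accepted as successful mid-stands, with
  onset/offset localization of stand-start and sit-end.
* **Features** — a frozen roster (38 torso / 20 thigh) covering timing
  (mean/SD/CoV of SSS, rise and descent durations), amplitudes at the
  fiducial points, postural sway (per-axis RMS), smoothness (jerk and
  angular-acceleration RMS) and complexity (normalized spectral entropy).
* **Reliability & exploration** — ICC(2,k) two-way random-effects
  absolute-agreement reliability with Shrout–Fleiss F-based intervals and
  the 0.5/0.75/0.9 bands; Spearman correlations vs MMSE and BBS; Wilcoxon
  faller vs non-faller tests; chi-square arm comparisons.
* **Estimation** — nested 10-fold CV logistic classification with
  sequential forward selection (balance impairment BBS < 53, cognitive
  impairment MMSE < 27, faller status), and elastic-net penalised Poisson
  regression (α = 0.1, model size 3–20) estimating BBS and MMSE scores.
  Every model is constrained to include the total test time, selection
  happens strictly inside training folds, and metrics come from pooled
  held-out predictions.
* **Synthetic data** — a generator producing FTSS recordings with
  ground-truth fiducials and cohorts with known outcome-generating
  coefficients, so the whole chain is testable without restricted clinical
  data.

## Worked example

```r
library(sitstand)

sim <- simulate_ftss_recording(synthesis_config(seed = 42), "torso")
sim$recording
#> <imu_recording> subject sim trial t1 (torso sensor)
#>   2031 samples, 19.82 s at 102.4 Hz nominal

res <- process_recording(sim$recording)   # filter -> trim -> validate -> segment -> extract
res$validity
#> <validity_report> overall: pass
#>   spikes: pass (0)
#>   orientation: pass (skewness 0.07)
#>   dropout: pass (max gap 1.0 intervals)

res$fiducials
#> <fiducial_set> 5 sit-stand-sit cycle(s) from torso sensor
#>   stand_start_s mid_stand_s sit_end_s
#> 1         0.996       2.217     3.740
#> 2         4.531       5.547     6.777
#> 3         7.617       8.760    10.117
#> 4        11.006      12.158    13.564
#> 5        14.326      15.488    16.826

round(unclass(res$features)[c("total_time", "sss_time_mean", "sss_time_cov",
                              "accel_rms_z", "jerk_rms_z",
                              "spec_entropy_accel_z")], 3)
#>           total_time        sss_time_mean         sss_time_cov
#>               15.830                2.510                0.071
#>          accel_rms_z           jerk_rms_z spec_entropy_accel_z
#>                1.116                3.486                0.209
```

The five detected cycles land within a few milliseconds of the generator's
scheduled events (time is re-referenced after the 1 s settling trim). The
subject "completed" the test in 15.8 s with a mean SSS cycle of 2.5 s and
low cycle-to-cycle variability (CoV 0.07); the RMS and jerk values
summarize trunk sway and movement smoothness over the task, and the low
spectral entropy (0.21) says the movement is strongly periodic rather than
noise-like.

Cohort-level analysis runs the same stages over a simulated study and fits
all five models:

```r
out <- run_pipeline(default_config(seed = 1), "run1")
out$classification$balance   # pooled 10-fold CV metrics
out$regression$bbs           # R2 / RMSE / Spearman rho / model size
```

A thin command-line wrapper with `simulate`, `segment`, `extract` and
`run-all` subcommands is installed at `inst/cli/sitstand.R`.

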