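Package: sitstand
Title: Quantifying the Five Times Sit-to-Stand Test from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to process torso- and thigh-mounted inertial measurement
    unit (IMU) recordings of the five times sit-to-stand test (FTSS).
    Provides calibration, zero-phase Butterworth band-pass filtering and
    settling-time trimming of raw accelerometer/gyroscope traces; adaptive
    peak-detection segmentation of each sit-stand-sit cycle into stand-start,
    mid-stand and sit-end fiducial times with signal-validity gating; a frozen
    roster of timing, postural-sway, jerk, fiducial-amplitude and
    spectral-entropy features; intra-session reliability via ICC(2,k) with
    F-based confidence intervals; Spearman/Wilcoxon/chi-square exploratory
    statistics; nested cross-validated logistic classification with
    sequential forward feature selection and elastic-net penalised Poisson
    regression for estimating Berg Balance Scale and Mini-Mental State
    Examination scores and classifying balance impairment, cognitive decline
    and falls risk; and a synthetic FTSS generator with ground-truth
    fiducials and cohorts drawn from known outcome-generating models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
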