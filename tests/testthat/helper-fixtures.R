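# Shared fixtures built in code.

# Minimal synthetic recording with arbitrary channel content.
make_recording <- function(az = NULL, fs = 102.4, duration_s = 10,
                           location = "torso", t = NULL) {
  if (is.null(t)) t <- seq(0, duration_s, by = 1 / fs)
  T <- length(t)
  accel <- matrix(0, T, 3)
  gyro <- matrix(0, T, 3)
  if (!is.null(az)) {
    stopifnot(length(az) == T)
    if (location == "torso") accel[, 3] <- az else accel[, 2] <- az
  }
  imu_recording("test", "t1", location, fs, t, accel, gyro)
}

# Simulate, filter and trim one trial; returns the processed recording plus
# ground-truth fiducials shifted onto the trimmed time base.
simulate_processed <- function(seed, location = "torso", n_cycles = 5,
                               cycle_duration_mean_s = 2.4,
                               sway_noise_rms = 0.05, ...) {
  cfg <- synthesis_config(
    n_cycles = n_cycles, cycle_duration_mean_s = cycle_duration_mean_s,
    sway_noise_rms = sway_noise_rms, seed = seed,
    trough_accel = if (location == "torso") -1.6 else -3.0, ...
  )
  sim <- simulate_ftss_recording(cfg, location)
  res <- process_recording(sim$recording)
  gt <- sim$fiducials$cycles - res$time_offset_s
  list(sim = sim, res = res, gt = gt)
}

# Independent ICC(2,k) oracle: two-way ANOVA mean squares by explicit sums
# (no call to aov/lm), then the agreement/average-measures definition.
icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - row_m[i] - col_m[j] + grand)^2
    }
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# A cohort table with chosen outcome columns.
make_cohort <- function(n, mmse = NULL, bbs = NULL, falls = NULL,
                        injurious = NULL, sex = NULL, arm = NULL) {
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = rep(75, n),
    sex = sex %||% rep(c("male", "female"), length.out = n),
    height_cm = rep(170, n),
    weight_kg = rep(70, n),
    mmse = mmse %||% rep(28, n),
    bbs = bbs %||% rep(54, n),
    falls_12mo = falls %||% rep(0, n),
    injurious_fall = injurious %||% rep(FALSE, n),
    arm = arm %||% rep("clinic", n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
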