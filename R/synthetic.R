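#' Configuration for a simulated FTSS recording
#'
#' The generator emulates the morphology of torso and thigh accelerometer
#' traces during the five-times sit-to-stand test: per cycle, the torso
#' Z-axis shows a positive pulse at stand-start, a negative trough at
#' mid-stand and a positive pulse at sit-end; the thigh Y-axis shows a
#' sustained negative excursion spanning the cycle with its deepest trough at
#' mid-stand. Pulses are Gaussian-windowed half-cosines (smooth and
#' band-limited within 0.01-5 Hz); additive sway noise is band-limited to the
#' same band. Defaults reflect the typical amplitudes seen on older adults:
#' torso peaks near 2 m/s^2 with troughs near -1.6 m/s^2, thigh minima near
#' -3 m/s^2, cycles of 1.5-3.5 s separated by brief (~0.8 s) seated pauses.
#'
#' @param n_cycles number of sit-stand-sit cycles (5 for a standard FTSS).
#' @param cycle_duration_mean_s,cycle_duration_sd_s cycle duration
#'   distribution, s; draws are clipped to \[1.5, 3.5\] s.
#' @param rise_fraction fraction of the cycle from stand-start to mid-stand.
#' @param peak_accel torso stand-start/sit-end pulse amplitude, m/s^2.
#' @param trough_accel mid-stand trough amplitude, m/s^2 (negative). For the
#'   thigh this is the trial's deepest Y-axis acceleration.
#' @param sway_noise_rms RMS of additive band-limited sway noise, m/s^2.
#' @param inter_cycle_gap_s mean seated pause between cycles, s (jittered
#'   +/- 0.1 s).
#' @param pre_post_sit_s quiet sitting padding before and after the test, s.
#' @param amp_jitter per-event relative amplitude jitter (SD); draws clipped
#'   to +/- 2 SD so every trough stays inside the adaptive thresholds.
#' @param artifact optional artifact to inject: `list(type = "spike",
#'   magnitude = <m/s^2>)`, `list(type = "dropout", duration_s = <s>)` or
#'   `list(type = "aborted_rise", fraction = <relative amplitude>)` (an extra
#'   sub-threshold attempt appended after the last cycle).
#' @param sampling_rate_hz sampling rate, Hz.
#' @param seed integer seed; the same configuration always yields a
#'   bit-identical recording.
#' @return an object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_cycles = 5,
                             cycle_duration_mean_s = 2.4,
                             cycle_duration_sd_s = 0.25,
                             rise_fraction = 0.45,
                             peak_accel = 2.0,
                             trough_accel = -1.6,
                             sway_noise_rms = 0.05,
                             inter_cycle_gap_s = 0.8,
                             pre_post_sit_s = 2.0,
                             amp_jitter = 0.015,
                             artifact = NULL,
                             sampling_rate_hz = 102.4,
                             seed = 1) {
  stopifnot(n_cycles >= 1, cycle_duration_mean_s > 0,
            rise_fraction > 0, rise_fraction < 1,
            trough_accel < 0, peak_accel > 0, sway_noise_rms >= 0)
  structure(
    list(n_cycles = n_cycles,
         cycle_duration_mean_s = cycle_duration_mean_s,
         cycle_duration_sd_s = cycle_duration_sd_s,
         rise_fraction = rise_fraction,
         peak_accel = peak_accel,
         trough_accel = trough_accel,
         sway_noise_rms = sway_noise_rms,
         inter_cycle_gap_s = inter_cycle_gap_s,
         pre_post_sit_s = pre_post_sit_s,
         amp_jitter = amp_jitter,
         artifact = artifact,
         sampling_rate_hz = sampling_rate_hz,
         seed = as.integer(seed)),
    class = "synthesis_config"
  )
}

# Gaussian-windowed half-cosine pulse, peak 1 at centre, zero outside
# |t - centre| > half_width.
ftss_pulse <- function(t, centre, half_width) {
  u <- (t - centre) / half_width
  out <- numeric(length(t))
  inside <- abs(u) < 1
  out[inside] <- cos(pi * u[inside] / 2) * exp(-u[inside]^2 / 0.5)
  out
}

# Cosine-ramped (Tukey) window equal to 1 on the plateau, 0 outside
# [from, to], with ramps of `ramp_s` seconds.
tukey_window <- function(t, from, to, ramp_s = 0.2) {
  out <- numeric(length(t))
  inside <- t >= from & t <= to
  out[inside] <- 1
  up <- t >= from & t < from + ramp_s
  out[up] <- 0.5 * (1 - cos(pi * (t[up] - from) / ramp_s))
  down <- t > to - ramp_s & t <= to
  out[down] <- 0.5 * (1 - cos(pi * (to - t[down]) / ramp_s))
  out
}

# Band-limited noise emulating postural sway, whose power is concentrated
# below ~2.5 Hz in standing older adults.
band_limited_noise <- function(n, fs, rms, band = c(0.1, 2.5)) {
  if (rms <= 0) {
    return(numeric(n))
  }
  bf <- ftss_bandpass_design(band[1], band[2], fs)
  w <- signal::filtfilt(bf, stats::rnorm(n))
  w * rms / sqrt(mean(w^2))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate one FTSS recording with ground-truth fiducials
#'
#' Builds the primary acceleration channel from the scheduled cycle events
#' (see [synthesis_config()]), a pitch gyroscope channel as a scaled
#' derivative of it, low-amplitude sway on the remaining channels, and
#' additive band-limited noise. Ground-truth fiducial times are the scheduled
#' stand-start, mid-stand and sit-end events.
#'
#' @param cfg a [synthesis_config()].
#' @param location `"torso"` or `"thigh"`.
#' @param subject_id,trial_id identifiers stamped on the recording.
#' @return a list with elements `recording` (an [imu_recording()]),
#'   `fiducials` (the ground-truth [fiducial_set()]) and `config`.
#' @export
simulate_ftss_recording <- function(cfg, location = c("torso", "thigh"),
                                    subject_id = "sim", trial_id = "t1") {
  stopifnot(inherits(cfg, "synthesis_config"))
  location <- match.arg(location)
  set.seed(cfg$seed)
  n <- cfg$n_cycles
  fs <- cfg$sampling_rate_hz

  durations <- clip(stats::rnorm(n, cfg$cycle_duration_mean_s,
                                 cfg$cycle_duration_sd_s), 1.5, 3.5)
  gaps <- if (n > 1) {
    stats::runif(n - 1, cfg$inter_cycle_gap_s - 0.1, cfg$inter_cycle_gap_s + 0.1)
  } else {
    numeric(0)
  }
  ss <- cfg$pre_post_sit_s + c(0, cumsum(durations[-n] + gaps))
  ms <- ss + cfg$rise_fraction * durations
  se <- ss + durations

  extra_tail <- 0
  abort <- !is.null(cfg$artifact) && identical(cfg$artifact$type, "aborted_rise")
  if (abort) {
    abort_frac <- cfg$artifact$fraction %||% 0.5
    abort_dur <- 1.6
    abort_ss <- se[n] + cfg$inter_cycle_gap_s
    extra_tail <- cfg$inter_cycle_gap_s + abort_dur
  }

  total <- cfg$pre_post_sit_s * 2 + sum(durations) + sum(gaps) + extra_tail
  tt <- seq(0, total, by = 1 / fs)
  T <- length(tt)
  jit <- function(k) clip(1 + stats::rnorm(k, 0, cfg$amp_jitter),
                          1 - 2 * cfg$amp_jitter, 1 + 2 * cfg$amp_jitter)

  primary <- numeric(T)
  if (location == "torso") {
    j_ss <- jit(n); j_ms <- jit(n); j_se <- jit(n)
    for (i in seq_len(n)) {
      primary <- primary +
        cfg$peak_accel * j_ss[i] * ftss_pulse(tt, ss[i], 0.22 * durations[i]) +
        cfg$trough_accel * j_ms[i] * ftss_pulse(tt, ms[i], 0.30 * durations[i]) +
        cfg$peak_accel * j_se[i] * ftss_pulse(tt, se[i], 0.22 * durations[i])
    }
    if (abort) {
      a_ms <- abort_ss + cfg$rise_fraction * abort_dur
      primary <- primary +
        abort_frac * cfg$peak_accel * ftss_pulse(tt, abort_ss, 0.22 * abort_dur) +
        abort_frac * cfg$trough_accel * ftss_pulse(tt, a_ms, 0.30 * abort_dur)
    }
  } else {
    # A shallow sustained plateau spanning the cycle (femoral axis leaves the
    # vertical while off the chair) plus a dominant mid-stand trough. The
    # plateau is kept shallow so the long-period content surviving the
    # 0.01 Hz high-pass edge does not modulate trough depths across cycles.
    depth <- abs(cfg$trough_accel)
    j_cy <- jit(n)
    for (i in seq_len(n)) {
      primary <- primary - j_cy[i] *
        (0.3 * depth * tukey_window(tt, ss[i], se[i], ramp_s = 0.1) +
           0.7 * depth * ftss_pulse(tt, ms[i], 0.25 * durations[i]))
    }
    if (abort) {
      a_se <- abort_ss + abort_dur
      a_ms <- abort_ss + cfg$rise_fraction * abort_dur
      primary <- primary - abort_frac *
        (0.3 * depth * tukey_window(tt, abort_ss, a_se, ramp_s = 0.1) +
           0.7 * depth * ftss_pulse(tt, a_ms, 0.25 * abort_dur))
    }
  }

  # pitch angular velocity: scaled central-difference derivative of the
  # primary channel (deg/s)
  pitch <- 12 * central_diff(primary, 1 / fs)

  accel <- matrix(0, T, 3)
  gyro <- matrix(0, T, 3)
  pc <- if (location == "torso") 3L else 2L
  accel[, pc] <- primary + band_limited_noise(T, fs, cfg$sway_noise_rms)
  for (k in setdiff(1:3, pc)) {
    accel[, k] <- band_limited_noise(T, fs, 0.6 * max(cfg$sway_noise_rms, 0.02))
  }
  gyro[, 2] <- pitch + band_limited_noise(T, fs, 1.0)
  gyro[, 1] <- band_limited_noise(T, fs, 0.8)
  gyro[, 3] <- band_limited_noise(T, fs, 0.8)

  keep <- rep(TRUE, T)
  if (!is.null(cfg$artifact)) {
    if (identical(cfg$artifact$type, "spike")) {
      at <- sample(which(tt > ss[1] & tt < se[n]), 1)
      accel[at, pc] <- accel[at, pc] +
        (cfg$artifact$magnitude %||% (30 * stats::sd(accel[, pc])))
    } else if (identical(cfg$artifact$type, "dropout")) {
      dur_gap <- cfg$artifact$duration_s %||% 0.5
      start <- stats::runif(1, ss[1], se[n] - dur_gap)
      keep <- !(tt > start & tt < start + dur_gap)
    }
  }

  rec <- imu_recording(
    subject_id = subject_id, trial_id = trial_id,
    sensor_location = location, sampling_rate_hz = fs,
    time_s = tt[keep],
    accel = accel[keep, , drop = FALSE],
    gyro = gyro[keep, , drop = FALSE]
  )
  fid <- fiducial_set(
    data.frame(stand_start_s = ss, mid_stand_s = ms, sit_end_s = se),
    source = location
  )
  list(recording = rec, fiducials = fid, config = cfg)
}

#' Configuration for a simulated FTSS cohort
#'
#' Defines a cohort whose clinical outcomes are generated from known
#' coefficient vectors on subject-level kinematic truth, so downstream
#' models can be checked against the generating process. Per subject, mean
#' cycle duration, rise fraction and movement amplitude are drawn once;
#' MMSE and BBS are Poisson draws (ceilings 30 and 56) from a log-linear
#' predictor on the z-scored true features, and faller status is a Bernoulli
#' draw from a logistic predictor.
#'
#' @param n_subjects cohort size (the study design uses 168).
#' @param sex_ratio proportion of female subjects.
#' @param trials_per_subject repeated FTSS trials per subject.
#' @param n_cycles sit-stand-sit cycles per trial.
#' @param true_coefficients named list with elements `mmse`, `bbs`, `falls`,
#'   each a named numeric vector of coefficients on z-scored true features
#'   (names from: `total_time`, `sss_time_mean`, `rise_time_mean`,
#'   `descent_time_mean`, `accel_midstand_mean`, `accel_standstart_mean`).
#' @param mmse_mean,bbs_mean Poisson means at covariate zero.
#' @param faller_rate marginal faller probability at covariate zero.
#' @param sway_noise_rms noise level passed to the signal generator.
#' @param location sensor placement for generated recordings.
#' @param prop_home proportion of subjects assessed at home (study arm).
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 168,
                          sex_ratio = 0.5,
                          trials_per_subject = 3,
                          n_cycles = 5,
                          true_coefficients = list(
                            mmse = c(total_time = -0.04),
                            bbs = c(total_time = -0.08, rise_time_mean = -0.03),
                            falls = c(total_time = 0.5)
                          ),
                          mmse_mean = 28, bbs_mean = 52, faller_rate = 0.48,
                          sway_noise_rms = 0.05,
                          location = c("torso", "thigh"),
                          prop_home = 40 / 168,
                          seed = 1) {
  location <- match.arg(location)
  structure(
    list(n_subjects = n_subjects, sex_ratio = sex_ratio,
         trials_per_subject = trials_per_subject, n_cycles = n_cycles,
         true_coefficients = true_coefficients,
         mmse_mean = mmse_mean, bbs_mean = bbs_mean, faller_rate = faller_rate,
         sway_noise_rms = sway_noise_rms, location = location,
         prop_home = prop_home, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate an FTSS cohort with known outcome-generating models
#'
#' @param cfg a [cohort_config()].
#' @param generate_signals when `TRUE`, raw IMU recordings are generated for
#'   every subject and trial (slower); when `FALSE` only the cohort table and
#'   true feature matrix are returned.
#' @return a list with elements `cohort` (data.frame of one row per subject:
#'   demographics, MMSE, BBS, falls history, study arm), `true_features`
#'   (subjects x features matrix of generating kinematic truth),
#'   `recordings` (nested list `[[subject]][[trial]]` of
#'   [simulate_ftss_recording()] outputs, or `NULL`) and `truth` (the
#'   coefficient vectors and linear predictors used).
#' @export
simulate_cohort <- function(cfg, generate_signals = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects

  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "female", "male")
  age <- round(clip(stats::rnorm(n, 74, 7), 60, 90))
  height <- round(ifelse(sex == "male", stats::rnorm(n, 172, 7),
                         stats::rnorm(n, 160, 6)), 1)
  weight <- round(ifelse(sex == "male", stats::rnorm(n, 78, 12),
                         stats::rnorm(n, 68, 11)), 1)
  arm <- ifelse(seq_len(n) <= round(cfg$prop_home * n), "home", "clinic")

  # subject-level kinematic truth
  dur <- clip(stats::rnorm(n, 2.4, 0.35), 1.6, 3.4)
  rise <- clip(stats::rnorm(n, 0.45, 0.03), 0.35, 0.55)
  amp <- clip(stats::rnorm(n, 1, 0.08), 0.8, 1.2)
  peak0 <- 2.0
  trough0 <- if (cfg$location == "torso") -1.6 else -3.0

  true_features <- cbind(
    total_time = cfg$n_cycles * dur + (cfg$n_cycles - 1) * 0.8,
    sss_time_mean = dur,
    rise_time_mean = rise * dur,
    descent_time_mean = (1 - rise) * dur,
    accel_midstand_mean = trough0 * amp,
    accel_standstart_mean = peak0 * amp
  )
  z <- scale(true_features)

  lin_pred <- function(coefs) {
    if (is.null(coefs) || !length(coefs)) return(numeric(n))
    bad <- setdiff(names(coefs), colnames(z))
    if (length(bad)) {
      stop("unknown true-feature name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    drop(z[, names(coefs), drop = FALSE] %*% coefs)
  }
  eta_mmse <- log(cfg$mmse_mean) + lin_pred(cfg$true_coefficients$mmse)
  eta_bbs <- log(cfg$bbs_mean) + lin_pred(cfg$true_coefficients$bbs)
  eta_falls <- stats::qlogis(cfg$faller_rate) + lin_pred(cfg$true_coefficients$falls)

  mmse <- pmin(stats::rpois(n, exp(eta_mmse)), 30)
  bbs <- pmin(stats::rpois(n, exp(eta_bbs)), 56)
  faller <- stats::rbinom(n, 1, stats::plogis(eta_falls)) == 1

  falls_12mo <- integer(n)
  injurious <- logical(n)
  falls_12mo[faller] <- sample(1:3, sum(faller), replace = TRUE,
                               prob = c(0.3, 0.5, 0.2))
  injurious[faller] <- falls_12mo[faller] == 1  # single falls need injury
  multi <- faller & falls_12mo > 1
  injurious[multi] <- stats::runif(sum(multi)) < 0.3
  falls_12mo[!faller] <- stats::rbinom(sum(!faller), 1, 0.2)

  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, sex = sex, height_cm = height, weight_kg = weight,
    mmse = mmse, bbs = bbs, falls_12mo = falls_12mo,
    injurious_fall = injurious, arm = arm,
    stringsAsFactors = FALSE
  )

  recordings <- NULL
  if (generate_signals) {
    base <- as.numeric(cfg$seed)
    recordings <- lapply(seq_len(n), function(i) {
      lapply(seq_len(cfg$trials_per_subject), function(j) {
        trial_seed <- as.integer((base * 7919 + i * 101 + j) %% 2147483647L)
        tcfg <- synthesis_config(
          n_cycles = cfg$n_cycles,
          cycle_duration_mean_s = dur[i],
          cycle_duration_sd_s = 0.12,
          rise_fraction = rise[i],
          peak_accel = peak0 * amp[i],
          trough_accel = trough0 * amp[i],
          sway_noise_rms = cfg$sway_noise_rms,
          seed = trial_seed
        )
        simulate_ftss_recording(tcfg, cfg$location,
                                subject_id = cohort$subject_id[i],
                                trial_id = sprintf("T%d", j))
      })
    })
    names(recordings) <- cohort$subject_id
  }

  list(cohort = cohort,
       true_features = true_features,
       recordings = recordings,
       truth = list(coefficients = cfg$true_coefficients,
                    eta = cbind(mmse = eta_mmse, bbs = eta_bbs,
                                falls = eta_falls)))
}
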