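#' Timing features of a segmented FTSS trial
#'
#' Total test time (first stand-start to last sit-end), cycle count, and
#' mean / SD / coefficient of variation of the sit-stand-sit, rise
#' (stand-start to mid-stand) and descent (mid-stand to sit-end) durations.
#' SD and CoV are 0 for a single cycle. 11 features.
#'
#' @param fid a [fiducial_set()] with at least one cycle.
#' @return named numeric vector of 11 timing features (seconds; CoV and
#'   `n_cycles` unitless).
#' @export
timing_features <- function(fid) {
  stopifnot(inherits(fid, "fiducial_set"))
  if (fid$n_cycles < 1) {
    stop("empty fiducial set", call. = FALSE)
  }
  cy <- fid$cycles
  sss <- cy$sit_end_s - cy$stand_start_s
  rise <- cy$mid_stand_s - cy$stand_start_s
  descent <- cy$sit_end_s - cy$mid_stand_s
  msc <- function(x, prefix) {
    m <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else 0
    if (abs(m) < 1e-9) {
      stop("mean ", prefix, " duration is ~0; CoV undefined", call. = FALSE)
    }
    stats::setNames(c(m, s, s / m),
                    paste0(prefix, c("_mean", "_sd", "_cov")))
  }
  c(total_time = cy$sit_end_s[fid$n_cycles] - cy$stand_start_s[1],
    n_cycles = fid$n_cycles,
    msc(sss, "sss_time"), msc(rise, "rise_time"), msc(descent, "descent_time"))
}

# Central-difference derivative (one-sided at the ends).
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

rms <- function(x) sqrt(mean(x^2))

analysis_window <- function(rec, fid) {
  from <- fid$cycles$stand_start_s[1]
  to <- fid$cycles$sit_end_s[fid$n_cycles]
  which(rec$time_s >= from & rec$time_s <= to)
}

#' Postural sway and smoothness features (torso only)
#'
#' Per-axis RMS of acceleration and angular velocity over the task window
#' (first stand-start to last sit-end) quantify sway, and per-axis RMS of the
#' first time-derivative — jerk (m/s^3) for acceleration, angular
#' acceleration (deg/s^2) for the gyroscope — quantify movement smoothness.
#' Derivatives use central differences at the sampling rate. A thigh-mounted
#' sensor cannot meaningfully measure upper-body sway, so calling this on a
#' thigh recording is an error. 12 features.
#'
#' @param rec a torso [imu_recording()].
#' @param fid its [fiducial_set()].
#' @return named numeric vector of 12 features.
#' @export
sway_jerk_features <- function(rec, fid) {
  stopifnot(inherits(rec, "imu_recording"), inherits(fid, "fiducial_set"))
  if (rec$sensor_location != "torso") {
    stop("sway and jerk features are defined for the torso sensor only",
         call. = FALSE)
  }
  w <- analysis_window(rec, fid)
  dt <- 1 / rec$sampling_rate_hz
  ax <- c("x", "y", "z")
  out <- c(
    stats::setNames(apply(rec$accel[w, , drop = FALSE], 2, rms),
                    paste0("accel_rms_", ax)),
    stats::setNames(apply(rec$gyro[w, , drop = FALSE], 2, rms),
                    paste0("gyro_rms_", ax)),
    stats::setNames(
      apply(rec$accel[w, , drop = FALSE], 2, function(v) rms(central_diff(v, dt))),
      paste0("jerk_rms_", ax)),
    stats::setNames(
      apply(rec$gyro[w, , drop = FALSE], 2, function(v) rms(central_diff(v, dt))),
      paste0("angacc_rms_", ax))
  )
  out
}

#' Normalized spectral entropy of a signal
#'
#' Shannon entropy of the normalized power spectral density (periodogram via
#' FFT, DC bin excluded), divided by the log of the number of frequency bins
#' so the result lies in \[0, 1\]: low for periodic movement, high for
#' noise-like movement. Used as a movement-complexity measure.
#'
#' @param x uniformly sampled numeric signal, length >= 64, non-constant.
#' @return unitless scalar in \[0, 1\].
#' @export
spectral_entropy <- function(x) {
  if (length(x) < 64) {
    stop("spectral entropy needs at least 64 samples", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12) {
    stop("spectral entropy is undefined for a constant signal", call. = FALSE)
  }
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  p <- p[2:floor(n / 2 + 1)]  # one-sided, DC excluded
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

#' Signal amplitudes at the fiducial points
#'
#' "Stand speed" and "endurance" measures: the primary acceleration channel
#' (torso Z / thigh Y) and the pitch angular-velocity channel sampled at each
#' fiducial time, summarized as mean and SD across cycles. The pitch axis is
#' chosen per trial as the gyroscope axis with maximal variance over the task
#' window, which is robust to mounting variation. Torso: 3 fiducials x 2
#' signals x 2 statistics = 12 features; thigh: stand-start and mid-stand
#' only, 8 features.
#'
#' @param rec an [imu_recording()].
#' @param fid its [fiducial_set()].
#' @return named numeric vector (12 torso / 8 thigh features).
#' @export
fiducial_amplitude_features <- function(rec, fid) {
  stopifnot(inherits(rec, "imu_recording"), inherits(fid, "fiducial_set"))
  cy <- fid$cycles
  tr <- range(rec$time_s)
  all_t <- unlist(cy)
  if (any(all_t < tr[1] - 1e-9 | all_t > tr[2] + 1e-9)) {
    stop("fiducial time outside the recording span", call. = FALSE)
  }
  w <- analysis_window(rec, fid)
  pitch_axis <- which.max(apply(rec$gyro[w, , drop = FALSE], 2, stats::var))
  acc <- primary_channel(rec)
  gyr <- rec$gyro[, pitch_axis]
  at <- function(signal, times) {
    idx <- vapply(times, function(ti) which.min(abs(rec$time_s - ti)), integer(1))
    signal[idx]
  }
  fids <- if (rec$sensor_location == "torso") {
    c(standstart = "stand_start_s", midstand = "mid_stand_s", sitend = "sit_end_s")
  } else {
    c(standstart = "stand_start_s", midstand = "mid_stand_s")
  }
  out <- numeric(0)
  for (sig_name in c("accel", "gyro")) {
    sig <- if (sig_name == "accel") acc else gyr
    for (k in seq_along(fids)) {
      v <- at(sig, cy[[fids[k]]])
      s <- if (length(v) > 1) stats::sd(v) else 0
      out <- c(out, stats::setNames(
        c(mean(v), s),
        paste0(sig_name, "_", names(fids)[k], c("_mean", "_sd"))))
    }
  }
  attr(out, "pitch_axis") <- pitch_axis
  out
}

#' Extract the full feature roster for one FTSS trial
#'
#' Assembles the location-specific roster with a frozen, deterministic
#' feature order. Torso (38 features): timing (11), fiducial amplitudes (12),
#' acceleration and angular-velocity RMS (6), jerk and angular-acceleration
#' RMS (6), spectral entropy of the three acceleration axes (3). Thigh
#' (20 features): timing (11), fiducial amplitudes (8), spectral entropy of
#' the femoral acceleration channel (1). The roster version is recorded so
#' serialized feature sets remain comparable.
#'
#' @param rec a validated [imu_recording()].
#' @param fid its [fiducial_set()].
#' @return an object of class `feature_vector`: a named numeric vector with
#'   attributes `sensor_location` and `roster_version`.
#' @export
extract_features <- function(rec, fid) {
  stopifnot(inherits(rec, "imu_recording"), inherits(fid, "fiducial_set"))
  w <- analysis_window(rec, fid)
  vals <- c(timing_features(fid), fiducial_amplitude_features(rec, fid))
  if (rec$sensor_location == "torso") {
    vals <- c(vals, sway_jerk_features(rec, fid),
              stats::setNames(
                apply(rec$accel[w, , drop = FALSE], 2, spectral_entropy),
                paste0("spec_entropy_accel_", c("x", "y", "z"))))
    expected <- 38L
  } else {
    vals <- c(vals, spec_entropy_accel_y = spectral_entropy(rec$accel[w, 2]))
    expected <- 20L
  }
  attributes(vals) <- list(names = names(vals))
  if (length(vals) != expected || anyNA(vals)) {
    stop("internal roster error: expected ", expected,
         " finite features, got ", length(vals), call. = FALSE)
  }
  structure(vals,
            class = "feature_vector",
            sensor_location = rec$sensor_location,
            roster_version = "reconstructed-v1")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features (%s roster %s)\n",
              length(x), attr(x, "sensor_location"),
              attr(x, "roster_version")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Names of the frozen feature roster
#'
#' @param location `"torso"` or `"thigh"`.
#' @return character vector of 38 (torso) or 20 (thigh) feature names in the
#'   frozen order.
#' @export
feature_roster <- function(location = c("torso", "thigh")) {
  location <- match.arg(location)
  timing <- c("total_time", "n_cycles",
              paste0(rep(c("sss_time", "rise_time", "descent_time"), each = 3),
                     c("_mean", "_sd", "_cov")))
  if (location == "torso") {
    amp <- paste0(rep(c("accel", "gyro"), each = 6), "_",
                  rep(rep(c("standstart", "midstand", "sitend"), each = 2), 2),
                  c("_mean", "_sd"))
    c(timing, amp,
      paste0("accel_rms_", c("x", "y", "z")),
      paste0("gyro_rms_", c("x", "y", "z")),
      paste0("jerk_rms_", c("x", "y", "z")),
      paste0("angacc_rms_", c("x", "y", "z")),
      paste0("spec_entropy_accel_", c("x", "y", "z")))
  } else {
    amp <- paste0(rep(c("accel", "gyro"), each = 4), "_",
                  rep(rep(c("standstart", "midstand"), each = 2), 2),
                  c("_mean", "_sd"))
    c(timing, amp, "spec_entropy_accel_y")
  }
}
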