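#' IMU recording container
#'
#' An `imu_recording` holds one five-times sit-to-stand (FTSS) trial recorded
#' by a single body-worn inertial measurement unit: a time base plus tri-axial
#' acceleration and tri-axial angular velocity. Torso sensors are mounted on
#' the sternum (Z axis approximately anteroposterior); thigh sensors along the
#' lateral thigh (Y axis approximately femoral / longitudinal).
#'
#' @param subject_id,trial_id character identifiers.
#' @param sensor_location `"torso"` or `"thigh"`.
#' @param sampling_rate_hz nominal sampling rate in Hz (devices here record at
#'   102.4 Hz).
#' @param time_s strictly increasing numeric vector of sample times (s).
#' @param accel T x 3 numeric matrix of acceleration, m/s^2 (columns X, Y, Z).
#' @param gyro T x 3 numeric matrix of angular velocity, deg/s.
#' @param processing character vector of processing steps already applied
#'   (internal bookkeeping; the pipeline order calibrate -> filter -> trim is
#'   enforced through it).
#'
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, trial_id, sensor_location,
                          sampling_rate_hz, time_s, accel, gyro,
                          processing = character()) {
  sensor_location <- match.arg(sensor_location, c("torso", "thigh"))
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  storage.mode(accel) <- "double"
  storage.mode(gyro) <- "double"
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      trial_id = as.character(trial_id),
      sensor_location = sensor_location,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      time_s = as.numeric(time_s),
      accel = accel,
      gyro = gyro,
      processing = processing
    ),
    class = "imu_recording"
  )
  validate_imu_recording(rec)
  rec
}

validate_imu_recording <- function(rec) {
  T <- length(rec$time_s)
  if (T < 2) {
    stop("imu_recording needs at least 2 samples", call. = FALSE)
  }
  if (nrow(rec$accel) != T || nrow(rec$gyro) != T) {
    stop("time_s, accel and gyro must have identical length", call. = FALSE)
  }
  if (ncol(rec$accel) != 3 || ncol(rec$gyro) != 3) {
    stop("accel and gyro must have 3 columns (X, Y, Z)", call. = FALSE)
  }
  dt <- diff(rec$time_s)
  if (any(dt <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number", call. = FALSE)
  }
  nominal <- 1 / rec$sampling_rate_hz
  if (abs(stats::median(dt) - nominal) > 0.05 * nominal) {
    stop("median sampling interval deviates more than 5% from 1/sampling_rate_hz",
         call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  dur <- x$time_s[length(x$time_s)] - x$time_s[1]
  cat(sprintf(
    "<imu_recording> subject %s trial %s (%s sensor)\n  %d samples, %.2f s at %.1f Hz nominal\n",
    x$subject_id, x$trial_id, x$sensor_location,
    length(x$time_s), dur, x$sampling_rate_hz
  ))
  if (length(x$processing)) {
    cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [imu_recording()].
#' @return numeric scalar, seconds between first and last sample.
#' @export
recording_duration <- function(rec) {
  rec$time_s[length(rec$time_s)] - rec$time_s[1]
}

#' Read an IMU trial from delimited text
#'
#' Expects a comma-separated file with a header row and columns
#' `time_s, ax, ay, az, gx, gy, gz`, one sample per line. Acceleration may be
#' recorded in g and angular velocity in rad/s; set the unit arguments and
#' they are converted to the package-standard m/s^2 and deg/s.
#'
#' @param path path to the CSV file.
#' @param location sensor placement, `"torso"` or `"thigh"`.
#' @param sampling_rate_hz nominal sampling rate (Hz).
#' @param accel_unit `"m/s2"` or `"g"`.
#' @param gyro_unit `"deg/s"` or `"rad/s"`.
#' @param subject_id,trial_id identifiers; default to the file name.
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, location, sampling_rate_hz = 102.4,
                           accel_unit = c("m/s2", "g"),
                           gyro_unit = c("deg/s", "rad/s"),
                           subject_id = NULL, trial_id = NULL) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("IMU file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  accel <- as.matrix(df[, c("ax", "ay", "az")])
  gyro <- as.matrix(df[, c("gx", "gy", "gz")])
  if (accel_unit == "g") accel <- accel * 9.80665
  if (gyro_unit == "rad/s") gyro <- gyro * 180 / pi
  stem <- sub("\\.[^.]*$", "", basename(path))
  imu_recording(
    subject_id = subject_id %||% stem,
    trial_id = trial_id %||% stem,
    sensor_location = location,
    sampling_rate_hz = sampling_rate_hz,
    time_s = df$time_s,
    accel = accel,
    gyro = gyro
  )
}

#' Write an IMU trial as delimited text
#'
#' Inverse of [read_recording()]; always writes package-standard units
#' (m/s^2, deg/s). Values are written in full double precision so a
#' write/read round trip is lossless to numerical precision.
#'
#' @param rec an [imu_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(
    time_s = rec$time_s,
    ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
    gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3]
  )
  # format() at 17 significant digits keeps the round trip exact in doubles
  out <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = TRUE), character(nrow(df)))
  writeLines(c(paste(names(df), collapse = ","),
               apply(out, 1, paste, collapse = ",")), path)
  invisible(path)
}

#' Sensor calibration parameters (Ferraris-style sensor model)
#'
#' Corrected samples are `matrix %*% (raw - offset)`, applied independently to
#' the accelerometer and gyroscope triads. The neutral calibration (identity
#' matrix, zero offset) leaves a recording unchanged.
#'
#' @param accel_offset,gyro_offset length-3 offsets (m/s^2, deg/s).
#' @param accel_matrix,gyro_matrix invertible 3 x 3 scale/alignment matrices.
#' @return an object of class `calibration_params`.
#' @export
calibration_params <- function(accel_offset = c(0, 0, 0),
                               accel_matrix = diag(3),
                               gyro_offset = c(0, 0, 0),
                               gyro_matrix = diag(3)) {
  accel_matrix <- as.matrix(accel_matrix)
  gyro_matrix <- as.matrix(gyro_matrix)
  for (m in list(accel_matrix, gyro_matrix)) {
    if (!all(dim(m) == c(3, 3))) {
      stop("calibration matrices must be 3 x 3", call. = FALSE)
    }
    if (abs(det(m)) < 1e-12) {
      stop("calibration matrix is singular", call. = FALSE)
    }
  }
  structure(
    list(accel_offset = as.numeric(accel_offset),
         accel_matrix = accel_matrix,
         gyro_offset = as.numeric(gyro_offset),
         gyro_matrix = gyro_matrix),
    class = "calibration_params"
  )
}

#' Apply a sensor calibration to a recording
#'
#' Must precede filtering and trimming; the pipeline order
#' calibrate -> filter -> trim is asserted.
#'
#' @param rec an [imu_recording()].
#' @param cal a [calibration_params()].
#' @return the calibrated [imu_recording()].
#' @export
apply_calibration <- function(rec, cal) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cal, "calibration_params"))
  if (any(c("bandpass", "trim") %in% rec$processing)) {
    stop("calibration must be applied before filtering and trimming",
         call. = FALSE)
  }
  rec$accel <- t(cal$accel_matrix %*% (t(rec$accel) - cal$accel_offset))
  rec$gyro <- t(cal$gyro_matrix %*% (t(rec$gyro) - cal$gyro_offset))
  rec$processing <- c(rec$processing, "calibrate")
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every acceleration and angular-velocity channel with a 2nd-order
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`), so
#' the effective response is 4th order with zero phase shift — fiducial timing
#' is preserved. The default 0.01–5 Hz band retains sit-to-stand movement
#' while rejecting the DC (gravity) component and high-frequency noise.
#'
#' @param rec an [imu_recording()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order filter order of the underlying one-pass design.
#' @return the filtered [imu_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 0.01, high_hz = 5.0, order = 2) {
  stopifnot(inherits(rec, "imu_recording"))
  if ("trim" %in% rec$processing) {
    stop("filtering must precede settling-time trimming", call. = FALSE)
  }
  fs <- rec$sampling_rate_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("need 0 < low_hz < high_hz < sampling_rate_hz / 2", call. = FALSE)
  }
  bf <- ftss_bandpass_design(low_hz, high_hz, fs, order)
  warmup <- 3 * (2 * order + 1)
  if (length(rec$time_s) <= warmup) {
    stop("signal shorter than the filter warm-up length", call. = FALSE)
  }
  # Reflection padding before the two-pass filter: the low band edge has a
  # time constant (~1/(2*pi*low_hz)) comparable to a trial's length, and with
  # zero initial conditions the slow pole's start-up transient would tilt the
  # baseline across the whole trial. Padding with the mirrored signal lets the
  # filter state settle before it reaches the real samples (the same edge
  # handling as Matlab/scipy filtfilt).
  n <- length(rec$time_s)
  pad <- min(n - 1, ceiling(3 * fs / (2 * pi * low_hz)))
  filt1 <- function(x) {
    xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  }
  rec$accel <- apply(rec$accel, 2, filt1)
  rec$gyro <- apply(rec$gyro, 2, filt1)
  rec$processing <- c(rec$processing, "bandpass")
  rec
}

# Band-pass design shared by the filter and its frequency-response tests.
ftss_bandpass_design <- function(low_hz, high_hz, fs, order = 2) {
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

#' Remove the sensor-settling interval at the start of a trial
#'
#' The first second of each trial is discarded to exclude spurious samples
#' from sensor settling; the time base is re-referenced so the first retained
#' sample is at t = 0.
#'
#' @param rec an [imu_recording()].
#' @param trim_s seconds to remove from the start (default 1).
#' @return the trimmed [imu_recording()].
#' @export
trim_settling <- function(rec, trim_s = 1.0) {
  stopifnot(inherits(rec, "imu_recording"), trim_s >= 0)
  if (trim_s == 0) {
    return(rec)
  }
  if (recording_duration(rec) <= trim_s) {
    stop("trial too short: duration must exceed trim_s", call. = FALSE)
  }
  keep <- rec$time_s >= rec$time_s[1] + trim_s
  rec$time_s <- rec$time_s[keep] - rec$time_s[keep][1]
  rec$accel <- rec$accel[keep, , drop = FALSE]
  rec$gyro <- rec$gyro[keep, , drop = FALSE]
  rec$processing <- c(rec$processing, "trim")
  validate_imu_recording(rec)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
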