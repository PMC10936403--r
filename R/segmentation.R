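#' Peak-detection parameters for FTSS segmentation
#'
#' Thresholds are fractions of each trial's own signal extremes, which makes
#' detection adaptive: positive torso peaks must exceed
#' `pos_threshold_frac * max(az)`, negative torso peaks must fall below
#' `neg_threshold_frac * min(az)`, and thigh mid-stand candidates must fall
#' below `thigh_midstand_frac * min(ay)`.
#'
#' @param pos_threshold_frac fraction of the torso Z-axis maximum (default 0.4).
#' @param neg_threshold_frac fraction of the torso Z-axis minimum (default 0.5).
#' @param thigh_midstand_frac fraction of the thigh Y-axis minimum (default 0.8).
#' @param min_cycle_separation_s refractory period between same-sign peaks, s.
#'   A physiological lower bound on sit-to-stand phase duration; suppresses
#'   noise doublets.
#' @param min_sss_duration_s minimum accepted sit-stand-sit cycle duration, s.
#'   Candidate cycles shorter than this are discarded as noise artifacts.
#' @param onset_frac thigh movement onset/offset threshold as a fraction of
#'   the trial's |Y-axis minimum|; stand-start / sit-end are the nearest
#'   points before/after mid-stand where |ay| drops below it.
#' @param smooth_s length (s) of the zero-phase moving average applied to the
#'   primary channel before peak detection. Sit-to-stand pulses are several
#'   times wider than this, so their amplitudes shrink only slightly and
#'   uniformly, while sway noise — which would otherwise inflate the trial
#'   extremes that the adaptive thresholds hang off — is strongly attenuated.
#'   Symmetric smoothing leaves peak timing unbiased.
#' @return an object of class `peak_params`.
#' @export
peak_params <- function(pos_threshold_frac = 0.4,
                        neg_threshold_frac = 0.5,
                        thigh_midstand_frac = 0.8,
                        min_cycle_separation_s = 0.5,
                        min_sss_duration_s = 1.0,
                        onset_frac = 0.1,
                        smooth_s = 0.25) {
  fr <- c(pos_threshold_frac, neg_threshold_frac, thigh_midstand_frac, onset_frac)
  if (any(fr <= 0 | fr >= 1)) {
    stop("threshold fractions must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(pos_threshold_frac = pos_threshold_frac,
         neg_threshold_frac = neg_threshold_frac,
         thigh_midstand_frac = thigh_midstand_frac,
         min_cycle_separation_s = min_cycle_separation_s,
         min_sss_duration_s = min_sss_duration_s,
         onset_frac = onset_frac,
         smooth_s = smooth_s),
    class = "peak_params"
  )
}

#' Fiducial times of sit-stand-sit cycles
#'
#' @param cycles data.frame with columns `stand_start_s`, `mid_stand_s`,
#'   `sit_end_s`, one row per detected cycle, time-ordered.
#' @param source `"torso"` or `"thigh"`.
#' @return an object of class `fiducial_set`.
#' @export
fiducial_set <- function(cycles, source) {
  source <- match.arg(source, c("torso", "thigh"))
  cycles <- as.data.frame(cycles)
  needed <- c("stand_start_s", "mid_stand_s", "sit_end_s")
  stopifnot(all(needed %in% names(cycles)))
  cycles <- cycles[order(cycles$mid_stand_s), needed, drop = FALSE]
  rownames(cycles) <- NULL
  if (nrow(cycles)) {
    ok <- cycles$stand_start_s < cycles$mid_stand_s &
      cycles$mid_stand_s < cycles$sit_end_s
    if (!all(ok)) {
      stop("each cycle must satisfy stand_start < mid_stand < sit_end",
           call. = FALSE)
    }
    if (nrow(cycles) > 1 &&
        any(cycles$sit_end_s[-nrow(cycles)] > cycles$stand_start_s[-1] + 1e-9)) {
      stop("cycles must be non-overlapping and time-ordered", call. = FALSE)
    }
  }
  structure(list(cycles = cycles, n_cycles = nrow(cycles), source = source),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d sit-stand-sit cycle(s) from %s sensor\n",
              x$n_cycles, x$source))
  print(round(x$cycles, 3))
  invisible(x)
}

#' Signal validity checks for an FTSS recording
#'
#' Three gates applied before segmentation (on unfiltered data, where spikes
#' and timestamp gaps are still sharp): a spike check for movement artifacts
#' (samples further than `spike_sd_mult` trial standard deviations from the
#' trial median on the primary channel), an orientation check that the
#' channel's morphological asymmetry matches the mounting (torso Z: positive
#' stand pulses outnumber mid-stand troughs two to one; thigh Y: the
#' mid-stand trough dominates the extremes), and a dropout check for
#' inter-sample gaps longer than `max_gap_intervals` nominal intervals.
#'
#' @param rec an [imu_recording()] (calibrated/filtered/trimmed upstream).
#' @param spike_sd_mult spike threshold in trial standard deviations.
#' @param max_gap_intervals dropout threshold in nominal sample intervals.
#' @return an object of class `validity_report` with elements `spike_check`,
#'   `orientation_check`, `dropout_check` (each pass/fail with a statistic)
#'   and `overall`, the conjunction of the three.
#' @export
check_validity <- function(rec, spike_sd_mult = 10, max_gap_intervals = 3) {
  stopifnot(inherits(rec, "imu_recording"))
  x <- primary_channel(rec)

  dev <- abs(x - stats::median(x))
  bound <- spike_sd_mult * stats::sd(x)
  n_spikes <- sum(dev > bound)
  spike <- list(pass = n_spikes == 0, n_spikes = n_spikes)

  # Orientation: sign conventions leave a morphological fingerprint. A
  # correctly mounted torso sensor shows two positive pulses (stand-start,
  # sit-end) per negative trough (mid-stand), so supra-threshold positive
  # peaks must be at least as frequent as negative ones. A thigh sensor's
  # femoral axis is dominated by the negative mid-stand trough, so its
  # extreme-value asymmetry must be negative. Whole-trial skewness is also
  # reported as a diagnostic, but is too weak a statistic to gate on: the
  # opposing pulse polarities within each cycle largely cancel its third
  # moment.
  xs <- smooth_ma(x - stats::median(x), rec$sampling_rate_hz, 0.25)
  skw <- e1071::skewness(x)
  if (max(xs) <= 0 || min(xs) >= 0) {
    orientation <- list(pass = FALSE, skewness = skw, asymmetry = NA_real_)
  } else if (rec$sensor_location == "torso") {
    n_pos <- length(find_threshold_peaks(xs, rec$time_s, 0.4 * max(xs), "max"))
    n_neg <- length(find_threshold_peaks(xs, rec$time_s, 0.5 * min(xs), "min"))
    orientation <- list(pass = n_pos >= n_neg, skewness = skw,
                        asymmetry = (n_pos - n_neg) / (n_pos + n_neg))
  } else {
    asym <- (max(xs) + min(xs)) / (max(xs) - min(xs))
    orientation <- list(pass = asym < 0.2, skewness = skw, asymmetry = asym)
  }

  gaps <- diff(rec$time_s)
  max_gap <- max(gaps) * rec$sampling_rate_hz
  dropout <- list(pass = max_gap <= max_gap_intervals, max_gap_intervals = max_gap)

  structure(
    list(spike_check = spike, orientation_check = orientation,
         dropout_check = dropout,
         overall = spike$pass && orientation$pass && dropout$pass),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  fmt <- function(p) if (p) "pass" else "FAIL"
  cat(sprintf(
    "<validity_report> overall: %s\n  spikes: %s (%d)\n  orientation: %s (skewness %.2f)\n  dropout: %s (max gap %.1f intervals)\n",
    fmt(x$overall), fmt(x$spike_check$pass), x$spike_check$n_spikes,
    fmt(x$orientation_check$pass), x$orientation_check$skewness,
    fmt(x$dropout_check$pass), x$dropout_check$max_gap_intervals
  ))
  invisible(x)
}

primary_channel <- function(rec) {
  if (rec$sensor_location == "torso") rec$accel[, 3] else rec$accel[, 2]
}

# Centered moving average (zero-phase); edges use shrinking windows.
smooth_ma <- function(x, fs, width_s) {
  k <- round(width_s * fs)
  if (k < 2) {
    return(x)
  }
  if (k %% 2 == 0) k <- k + 1
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  half <- (k - 1) / 2
  n <- length(x)
  for (i in seq_len(half)) {
    sm[i] <- mean(x[1:(i + half)])
    sm[n - i + 1] <- mean(x[(n - i + 1 - half):n])
  }
  as.numeric(sm)
}

# Threshold-crossing peak detector with step-back refinement.
#
# Finds contiguous runs of samples beyond `threshold` (above for
# direction = "max", below for "min"), takes the extremum of each run, then
# refines it by a step-back search: from the detected sample, walk towards
# neighbouring samples while they are more extreme, stopping at the first
# derivative sign change (ties broken by the earliest sample). Peaks of the
# same sign closer than `refractory_s` are merged, keeping the more extreme.
find_threshold_peaks <- function(x, time_s, threshold, direction = c("max", "min"),
                                 refractory_s = 0.5) {
  direction <- match.arg(direction)
  s <- if (direction == "max") x else -x
  thr <- if (direction == "max") threshold else -threshold
  beyond <- s > thr
  if (!any(beyond)) {
    return(integer(0))
  }
  n <- length(s)
  # every interior local maximum above the threshold (earliest sample of a
  # flat top); a run of supra-threshold samples may hold several distinct
  # peaks, e.g. sit-end and the next stand-start with a shallow valley
  cand <- which(beyond)
  cand <- cand[cand > 1 & cand < n]
  peaks <- cand[s[cand] > s[cand - 1] & s[cand] >= s[cand + 1]]
  # step-back refinement: a supra-threshold region clipped by the signal edge
  # has no interior extremum; walk from the crossing to the boundary extremum
  if (!length(peaks) && length(cand)) {
    peaks <- cand[which.max(s[cand])]
  }
  peaks <- sort(unique(peaks))
  # refractory merge: keep the more extreme of peaks closer than refractory_s
  if (length(peaks) > 1) {
    keep <- peaks[1]
    for (p in peaks[-1]) {
      last <- keep[length(keep)]
      if (time_s[p] - time_s[last] < refractory_s) {
        if (s[p] > s[last]) keep[length(keep)] <- p
      } else {
        keep <- c(keep, p)
      }
    }
    peaks <- keep
  }
  peaks
}

#' Segment an FTSS trial from the torso sensor
#'
#' Adaptive peak detection on the torso Z-axis acceleration. Positive peaks
#' exceeding `0.4 * max(az)` mark stand-start and sit-end; negative peaks
#' below `0.5 * min(az)` mark mid-stand. Alternation is enforced: each
#' accepted mid-stand is the most negative peak lying between a pair of
#' adjacent positive peaks, with the preceding positive peak taken as
#' stand-start and the following one as sit-end. Candidate cycles shorter
#' than `min_sss_duration_s` are discarded as sub-physiological.
#'
#' @param rec an [imu_recording()] from the torso.
#' @param params a [peak_params()].
#' @param validity a `validity_report`; computed from `rec` when omitted.
#'   Recordings failing validity are refused.
#' @return a [fiducial_set()].
#' @export
segment_torso <- function(rec, params = peak_params(),
                          validity = check_validity(rec)) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$sensor_location != "torso") {
    stop("segment_torso requires a torso recording", call. = FALSE)
  }
  if (!validity$overall) {
    stop("recording failed signal validity checks; refusing to segment",
         call. = FALSE)
  }
  az <- smooth_ma(rec$accel[, 3], rec$sampling_rate_hz, params$smooth_s)
  tt <- rec$time_s
  if (max(az) <= 0 || min(az) >= 0) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  pos_thr <- params$pos_threshold_frac * max(az)
  neg_thr <- params$neg_threshold_frac * min(az)
  pos <- find_threshold_peaks(az, tt, pos_thr, "max", params$min_cycle_separation_s)
  neg <- find_threshold_peaks(az, tt, neg_thr, "min", params$min_cycle_separation_s)
  if (length(pos) < 2 || length(neg) < 1) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  cand <- lapply(neg, function(j) {
    before <- pos[pos < j]
    after <- pos[pos > j]
    if (!length(before) || !length(after)) return(NULL)
    c(ss = before[length(before)], ms = j, se = after[1])
  })
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || !nrow(cand)) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  # one mid-stand per adjacent positive pair: keep the most negative
  key <- paste(cand[, "ss"], cand[, "se"])
  keep <- unlist(lapply(split(seq_len(nrow(cand)), key), function(rows) {
    rows[which.min(az[cand[rows, "ms"]])]
  }), use.names = FALSE)
  cand <- cand[sort(keep), , drop = FALSE]
  dur <- tt[cand[, "se"]] - tt[cand[, "ss"]]
  cand <- cand[dur >= params$min_sss_duration_s, , drop = FALSE]
  if (!nrow(cand)) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  fiducial_set(
    data.frame(stand_start_s = tt[cand[, "ss"]],
               mid_stand_s = tt[cand[, "ms"]],
               sit_end_s = tt[cand[, "se"]]),
    source = "torso"
  )
}

#' Segment an FTSS trial from the thigh sensor
#'
#' Peak detection on the femoral (Y-axis) acceleration. The trial's global
#' minimum defines the adaptive threshold: local minima with acceleration
#' below `0.8 * min(ay)` are accepted as mid-stand points of successful
#' sit-stand-sit attempts; shallower dips (e.g. aborted rises) are rejected.
#' Stand-start and sit-end are located as movement onset/offset: the nearest
#' samples before/after each mid-stand where `|ay|` falls below
#' `onset_frac * |min(ay)|`.
#'
#' @inheritParams segment_torso
#' @return a [fiducial_set()].
#' @export
segment_thigh <- function(rec, params = peak_params(),
                          validity = check_validity(rec)) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$sensor_location != "thigh") {
    stop("segment_thigh requires a thigh recording", call. = FALSE)
  }
  if (!validity$overall) {
    stop("recording failed signal validity checks; refusing to segment",
         call. = FALSE)
  }
  ay <- smooth_ma(rec$accel[, 2], rec$sampling_rate_hz, params$smooth_s)
  tt <- rec$time_s
  ay_min <- min(ay)
  if (ay_min >= 0) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  ms_thr <- params$thigh_midstand_frac * ay_min
  # accepted mid-stands separated by at least the minimum cycle duration
  mids <- find_threshold_peaks(ay, tt, ms_thr, "min",
                               refractory_s = params$min_sss_duration_s)
  if (!length(mids)) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  # Movement onset/offset is referenced to the seated baseline: after
  # band-pass filtering the DC level is arbitrary, so "near rest" cannot mean
  # near literal zero. The protocol starts every trial seated, so the median
  # of the first half second estimates the resting level.
  baseline <- stats::median(ay[tt <= tt[1] + 0.5])
  onset_bound <- params$onset_frac * abs(ay_min - baseline)
  quiet <- abs(ay - baseline) < onset_bound
  cycles <- lapply(mids, function(j) {
    before <- which(quiet[seq_len(j - 1)])
    after <- which(quiet[seq(j + 1, length(ay))]) + j
    if (!length(before) || !length(after)) return(NULL)
    data.frame(stand_start_s = tt[before[length(before)]],
               mid_stand_s = tt[j],
               sit_end_s = tt[after[1]])
  })
  cycles <- do.call(rbind, cycles[!vapply(cycles, is.null, logical(1))])
  if (is.null(cycles) || !nrow(cycles)) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  dur <- cycles$sit_end_s - cycles$stand_start_s
  cycles <- cycles[dur >= params$min_sss_duration_s, , drop = FALSE]
  if (!nrow(cycles)) {
    stop("no sit-to-stand transitions found", call. = FALSE)
  }
  fiducial_set(cycles, source = "thigh")
}

#' Segment an FTSS trial with the sensor-appropriate algorithm
#'
#' Dispatches to [segment_torso()] or [segment_thigh()] on the recording's
#' `sensor_location`.
#'
#' @inheritParams segment_torso
#' @return a [fiducial_set()].
#' @export
segment_recording <- function(rec, params = peak_params(),
                              validity = check_validity(rec)) {
  if (rec$sensor_location == "torso") {
    segment_torso(rec, params, validity)
  } else {
    segment_thigh(rec, params, validity)
  }
}
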