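test_that("clean recordings pass all validity checks", {
  for (loc in c("torso", "thigh")) {
    x <- simulate_processed(seed = 1, location = loc)
    expect_true(x$res$validity$overall)
  }
})

test_that("an injected spike fails the spike check with the right count", {
  cfg <- synthesis_config(seed = 3, artifact = list(type = "spike"))
  sim <- simulate_ftss_recording(cfg, "torso")
  res <- process_recording(sim$recording, cfg = default_config())
  # the spike survives filtering spread over a few samples; it must be
  # flagged and segmentation refused
  expect_false(res$validity$spike_check$pass)
  expect_gte(res$validity$spike_check$n_spikes, 1)
  expect_null(res$fiducials)

  # unfiltered, the spike is exactly one sample
  v <- check_validity(sim$recording)
  expect_false(v$spike_check$pass)
  expect_equal(v$spike_check$n_spikes, 1)
})

test_that("a timestamp gap fails the dropout check", {
  cfg <- synthesis_config(seed = 4, artifact = list(type = "dropout",
                                                    duration_s = 0.5))
  sim <- simulate_ftss_recording(cfg, "torso")
  v <- check_validity(sim$recording)
  expect_false(v$dropout_check$pass)
  expect_gt(v$dropout_check$max_gap_intervals, 3)
})

test_that("a flipped sensor fails the orientation check", {
  sim <- simulate_ftss_recording(synthesis_config(seed = 5), "torso")
  rec <- sim$recording
  rec$accel[, 3] <- -rec$accel[, 3]
  v <- check_validity(rec)
  expect_false(v$orientation_check$pass)
  expect_false(v$overall)
})

test_that("torso segmentation recovers clean five-cycle trials", {
  x <- simulate_processed(seed = 1, location = "torso")
  fid <- x$res$fiducials
  expect_equal(fid$n_cycles, 5)
  expect_lt(max(abs(as.matrix(fid$cycles) - as.matrix(x$gt))), 0.10)
})

test_that("torso peaks honor the adaptive threshold fractions", {
  x <- simulate_processed(seed = 8, location = "torso")
  rec <- x$res$recording
  az <- sitstand:::smooth_ma(rec$accel[, 3], rec$sampling_rate_hz, 0.25)
  fid <- x$res$fiducials
  at <- function(times) az[vapply(times, function(ti) {
    which.min(abs(rec$time_s - ti))
  }, integer(1))]
  expect_true(all(at(fid$cycles$stand_start_s) > 0.4 * max(az)))
  expect_true(all(at(fid$cycles$sit_end_s) > 0.4 * max(az)))
  expect_true(all(at(fid$cycles$mid_stand_s) < 0.5 * min(az)))
})

test_that("signals without transitions raise a segmentation error", {
  rec <- make_recording(az = rep(0, 1025))
  ok <- list(overall = TRUE)
  expect_error(segment_torso(rec, validity = ok), "no sit-to-stand")
  thigh <- make_recording(az = rep(0, 1025), location = "thigh")
  expect_error(segment_thigh(thigh, validity = ok), "no sit-to-stand")
})

test_that("sensor-location contracts are enforced", {
  sim <- simulate_ftss_recording(synthesis_config(seed = 2), "torso")
  expect_error(segment_thigh(sim$recording, validity = list(overall = TRUE)),
               "thigh recording")
  simt <- simulate_ftss_recording(synthesis_config(seed = 2,
                                                   trough_accel = -3),
                                  "thigh")
  expect_error(segment_torso(simt$recording, validity = list(overall = TRUE)),
               "torso recording")
  # validity failures are refused
  bad <- sim$recording
  bad$accel[, 3] <- -bad$accel[, 3]
  expect_error(segment_torso(bad), "validity")
})

test_that("thigh segmentation recovers clean trials", {
  x <- simulate_processed(seed = 2, location = "thigh")
  expect_equal(x$res$fiducials$n_cycles, 5)
  expect_lt(max(abs(as.matrix(x$res$fiducials$cycles) - as.matrix(x$gt))),
            0.10)
})

test_that("a half-amplitude aborted rise is rejected by the 0.8 rule", {
  cfg <- synthesis_config(seed = 6, trough_accel = -3,
                          artifact = list(type = "aborted_rise",
                                          fraction = 0.5))
  sim <- simulate_ftss_recording(cfg, "thigh")
  res <- process_recording(sim$recording)
  expect_equal(res$fiducials$n_cycles, 5)
  # the aborted attempt lies after the last genuine sit-end
  expect_true(all(res$fiducials$cycles$mid_stand_s <
                    max(sim$fiducials$cycles$sit_end_s)))
})

test_that("fiducial times are invariant to positive rescaling", {
  for (loc in c("torso", "thigh")) {
    x <- simulate_processed(seed = 9, location = loc)
    rec <- x$res$recording
    scaled <- rec
    scaled$accel <- scaled$accel * 3.7
    scaled$gyro <- scaled$gyro * 3.7
    f1 <- segment_recording(rec)
    f2 <- segment_recording(scaled)
    expect_equal(f1$cycles, f2$cycles)
  }
})

test_that("fiducial times are equivariant to time shifts", {
  x <- simulate_processed(seed = 10, location = "torso")
  rec <- x$res$recording
  shifted <- rec
  shifted$time_s <- shifted$time_s + 13.25
  f1 <- segment_recording(rec)
  f2 <- segment_recording(shifted)
  expect_equal(as.matrix(f2$cycles), as.matrix(f1$cycles) + 13.25,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("cycle counts degrade gracefully under moderate sway noise", {
  recover_rate <- function(loc, noise, seeds) {
    ok <- 0
    for (s in seeds) {
      set.seed(s)
      nc <- sample(3:8, 1)
      x <- try(simulate_processed(
        seed = s, location = loc, n_cycles = nc,
        cycle_duration_mean_s = runif(1, 1.8, 3.0),
        sway_noise_rms = noise
      ), silent = TRUE)
      if (!inherits(x, "try-error") && !is.null(x$res$fiducials) &&
          x$res$fiducials$n_cycles == nc) {
        ok <- ok + 1
      }
    }
    ok / length(seeds)
  }
  # torso tolerates sway up to ~15% of its pulse amplitude
  expect_gte(mean(c(recover_rate("torso", 0.1, 1:20),
                    recover_rate("torso", 0.2, 1:20),
                    recover_rate("torso", 0.3, 1:20))), 0.95)
  # the thigh acceptance band (0.8 of the deepest trough) leaves less
  # headroom; ~3% of the trough amplitude is still fully recovered
  expect_gte(mean(c(recover_rate("thigh", 0.05, 1:20),
                    recover_rate("thigh", 0.1, 1:20))), 0.95)
})

test_that("fiducial sets enforce ordering invariants", {
  expect_error(fiducial_set(data.frame(stand_start_s = 2, mid_stand_s = 1,
                                       sit_end_s = 3), "torso"),
               "stand_start < mid_stand < sit_end")
  expect_error(fiducial_set(data.frame(stand_start_s = c(0, 1.5),
                                       mid_stand_s = c(1, 2.5),
                                       sit_end_s = c(2, 3.5)), "torso"),
               "non-overlapping")
})
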