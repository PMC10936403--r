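#' Default pipeline configuration
#'
#' A fully serializable list of every stage parameter; a pipeline run is
#' reproducible from its configuration alone. Values can be overridden by
#' [modifyList()] or supplied from a YAML file via [load_config()].
#'
#' @param seed master seed for the run.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    sensor = "torso",
    cohort = list(n_subjects = 168, trials_per_subject = 3, n_cycles = 5,
                  sway_noise_rms = 0.05),
    filter = list(low_hz = 0.01, high_hz = 5.0),
    trim_s = 1.0,
    segmentation = list(pos_threshold_frac = 0.4, neg_threshold_frac = 0.5,
                        thigh_midstand_frac = 0.8),
    classification = list(outcomes = c("balance", "cognition", "falls"),
                          k_folds = 10, min_improve_pp = 0.5,
                          interactions = TRUE),
    regression = list(outcomes = c("bbs", "mmse"), alpha = 0.1,
                      size_bounds = c(3, 20), k_folds = 10)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected before any computation starts.
#'
#' @param path YAML file path.
#' @return configuration list (defaults overridden by the file).
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(base, user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$sensor %in% c("torso", "thigh")) {
    stop("config error: sensor must be 'torso' or 'thigh', got '",
         cfg$sensor, "'", call. = FALSE)
  }
  stopifnot(cfg$cohort$n_subjects >= 10, cfg$cohort$trials_per_subject >= 1)
  cfg
}

#' Process one raw recording through the fixed pipeline
#'
#' Calibrate, band-pass filter, trim the settling second, run validity
#' checks, segment and extract features.
#'
#' @param rec raw [imu_recording()].
#' @param cal optional [calibration_params()].
#' @param cfg configuration list (filter band, trim length).
#' @param params [peak_params()] for segmentation.
#' @return list with `recording` (processed), `validity`, `fiducials`,
#'   `features`, and `time_offset_s` (seconds removed from the front, for
#'   aligning fiducials with the raw time base); on validity failure
#'   `fiducials`/`features` are NULL.
#' @export
process_recording <- function(rec, cal = NULL, cfg = default_config(),
                              params = peak_params()) {
  if (!is.null(cal)) rec <- apply_calibration(rec, cal)
  # validity is assessed on the unfiltered data: a single-sample spike or a
  # timestamp gap is smeared beyond recognition by the band-pass filter
  validity <- check_validity(rec)
  if (!validity$overall) {
    return(list(recording = rec, validity = validity, fiducials = NULL,
                features = NULL, time_offset_s = 0))
  }
  t_raw0 <- rec$time_s[1]
  rec <- bandpass_filter(rec, cfg$filter$low_hz, cfg$filter$high_hz)
  offset <- 0
  if (cfg$trim_s > 0) {
    keep_from <- rec$time_s[rec$time_s >= t_raw0 + cfg$trim_s][1]
    rec <- trim_settling(rec, cfg$trim_s)
    offset <- keep_from
  }
  fid <- segment_recording(rec, params, validity)
  list(recording = rec, validity = validity, fiducials = fid,
       features = extract_features(rec, fid), time_offset_s = offset)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> segment -> extract -> reliability -> associations ->
#' classification -> regression and writes every report to `out_dir`,
#' together with a run manifest listing all outputs and per-stage counts.
#' Identical configuration yields byte-identical reports.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  write_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, name)
  }
  write_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, name)
  }

  say("simulate: ", config$cohort$n_subjects, " subjects, ",
      config$cohort$trials_per_subject, " trials (", config$sensor, ")")
  ccfg <- cohort_config(
    n_subjects = config$cohort$n_subjects,
    trials_per_subject = config$cohort$trials_per_subject,
    n_cycles = config$cohort$n_cycles,
    sway_noise_rms = config$cohort$sway_noise_rms,
    location = config$sensor,
    seed = config$seed
  )
  sim <- simulate_cohort(ccfg, generate_signals = TRUE)
  write_csv(sim$cohort, "cohort.csv")

  say("segment + extract")
  params <- do.call(peak_params, config$segmentation)
  n_invalid <- 0
  rows <- list()
  for (sid in names(sim$recordings)) {
    for (trial in sim$recordings[[sid]]) {
      res <- process_recording(trial$recording, cal = NULL, cfg = config,
                               params = params)
      if (is.null(res$features)) {
        n_invalid <- n_invalid + 1
        next
      }
      fv <- as.data.frame(as.list(unclass(res$features)))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject_id = trial$recording$subject_id,
                   trial_id = trial$recording$trial_id),
        fv
      )
    }
  }
  features <- do.call(rbind, rows)
  write_csv(features, "features.csv")
  say("  ", nrow(features), " trials extracted, ", n_invalid,
      " failed validity")

  say("reliability (ICC)")
  rel <- reliability_table(features)
  write_csv(rel, "reliability.csv")

  say("associations")
  assoc <- association_tests(sim$cohort, features)
  write_csv(assoc$features, "associations_features.csv")
  write_csv(assoc$arm, "associations_arm.csv")

  # first trial per subject for modeling
  first <- features[!duplicated(features$subject_id), ]
  feat_mat <- first[setdiff(names(first), "trial_id")]
  dm <- build_design_matrix(
    sim$cohort[sim$cohort$subject_id %in% first$subject_id, ],
    feat_mat, stratum = "pooled",
    interactions = isTRUE(config$classification$interactions),
    interaction_vars = c("total_time", "age", "sex", "height", "weight")
  )
  cohort_m <- sim$cohort[match(dm$subject_id, sim$cohort$subject_id), ]
  labels <- list(
    balance = as.integer(cohort_m$bbs < 53),
    cognition = as.integer(cohort_m$mmse < 27),
    falls = as.integer(label_faller(cohort_m$falls_12mo,
                                    cohort_m$injurious_fall))
  )

  class_reports <- list()
  for (outc in config$classification$outcomes) {
    say("classification: ", outc)
    rep <- sfs_logistic_cv(
      dm, labels[[outc]],
      k_folds = config$classification$k_folds,
      min_improve_pp = config$classification$min_improve_pp,
      seed = config$seed
    )
    class_reports[[outc]] <- rep
    write_json(list(outcome = outc, sensor = config$sensor,
                    stratum = "pooled",
                    metrics = as.list(rep$metrics),
                    confusion = as.list(rep$confusion),
                    selected_features = rep$selected_features),
               paste0("classification_", outc, ".json"))
  }

  scores <- list(bbs = cohort_m$bbs, mmse = cohort_m$mmse)
  reg_reports <- list()
  for (outc in config$regression$outcomes) {
    say("regression: ", outc)
    rep <- poisson_elastic_net_cv(
      dm, scores[[outc]],
      alpha = config$regression$alpha,
      size_bounds = config$regression$size_bounds,
      k_folds = config$regression$k_folds,
      seed = config$seed
    )
    reg_reports[[outc]] <- rep
    write_json(list(outcome = outc, sensor = config$sensor,
                    stratum = "pooled",
                    metrics = as.list(rep$metrics),
                    dof = rep$dof, dof_per_fold = rep$dof_per_fold,
                    selected_features = rep$selected_features),
               paste0("regression_", outc, ".json"))
  }

  manifest <- list(
    config = config,
    counts = list(trials_extracted = nrow(features),
                  trials_failed_validity = n_invalid,
                  subjects_modeled = nrow(cohort_m)),
    outputs = sort(outputs)
  )
  write_json(manifest, "manifest.json")

  invisible(list(cohort = sim$cohort, features = features,
                 reliability = rel, associations = assoc,
                 classification = class_reports, regression = reg_reports,
                 manifest = manifest))
}
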