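#' Read a cohort table of clinical covariates
#'
#' One row per subject with columns `subject_id, age, sex, height_cm,
#' weight_kg, mmse, bbs, falls_12mo, injurious_fall, arm`. MMSE is bounded by
#' 30, BBS by 56; falls counts are non-negative.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

validate_cohort <- function(df) {
  needed <- c("subject_id", "age", "sex", "height_cm", "weight_kg",
              "mmse", "bbs", "falls_12mo", "injurious_fall", "arm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$mmse < 0 | df$mmse > 30)) stop("mmse must be in 0-30", call. = FALSE)
  if (any(df$bbs < 0 | df$bbs > 56)) stop("bbs must be in 0-56", call. = FALSE)
  if (any(df$falls_12mo < 0)) stop("falls_12mo must be >= 0", call. = FALSE)
  if (!all(df$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  df$injurious_fall <- as.logical(df$injurious_fall)
  df
}

#' Faller classification from falls history
#'
#' A subject is a faller if they experienced more than one fall in the
#' previous 12 months, or any fall resulting in injury.
#'
#' @param falls_12mo number of falls in the previous 12 months.
#' @param injurious_fall whether any of those falls caused injury.
#' @return logical vector.
#' @export
label_faller <- function(falls_12mo, injurious_fall) {
  falls_12mo > 1 | (falls_12mo >= 1 & injurious_fall)
}

#' Dichotomize MMSE and BBS scores into impairment labels
#'
#' MMSE below 27 denotes impaired cognition; BBS below 53 denotes impaired
#' balance (standard literature cut-offs).
#'
#' @param mmse MMSE scores, 0-30.
#' @param bbs BBS scores, 0-56.
#' @return data.frame with logical columns `cognitive_impaired` and
#'   `balance_impaired`.
#' @export
dichotomize_scores <- function(mmse, bbs) {
  data.frame(cognitive_impaired = mmse < 27, balance_impaired = bbs < 53)
}

#' Exploratory association tests between features and clinical measures
#'
#' Features are first averaged per subject across trials, then each feature
#' is tested with Spearman's rank correlation against MMSE and BBS, and with
#' Wilcoxon's rank-sum test between fallers and non-fallers. Categorical
#' study-arm differences (sex and faller proportions between home and clinic
#' arms) use chi-square tests of proportions. No multiple-comparison
#' correction is applied.
#'
#' @param cohort validated cohort data.frame.
#' @param trial_features data.frame of one row per trial: `subject_id` plus
#'   numeric feature columns.
#' @return list with `features` (per-feature test table) and `arm`
#'   (chi-square comparisons between study arms). Constant features yield
#'   `NA` with `note = "constant feature"` rather than propagating NaN.
#' @export
association_tests <- function(cohort, trial_features) {
  cohort <- validate_cohort(cohort)
  stopifnot("subject_id" %in% names(trial_features))
  feat_cols <- setdiff(names(trial_features), c("subject_id", "trial_id"))
  # per-subject trial averages before any testing
  avg <- stats::aggregate(trial_features[feat_cols],
                          by = list(subject_id = trial_features$subject_id),
                          FUN = mean)
  merged <- merge(cohort, avg, by = "subject_id")
  faller <- label_faller(merged$falls_12mo, merged$injurious_fall)
  if (sum(faller) < 2 || sum(!faller) < 2) {
    stop("need at least 2 subjects in each faller group", call. = FALSE)
  }

  rows <- lapply(feat_cols, function(f) {
    x <- merged[[f]]
    if (stats::sd(x) < 1e-12) {
      return(data.frame(feature = f, mmse_rho = NA, mmse_p = NA,
                        bbs_rho = NA, bbs_p = NA, wilcoxon_w = NA,
                        faller_p = NA, note = "constant feature"))
    }
    ct_m <- suppressWarnings(
      stats::cor.test(x, merged$mmse, method = "spearman"))
    ct_b <- suppressWarnings(
      stats::cor.test(x, merged$bbs, method = "spearman"))
    wt <- suppressWarnings(stats::wilcox.test(x[faller], x[!faller]))
    data.frame(feature = f,
               mmse_rho = unname(ct_m$estimate), mmse_p = ct_m$p.value,
               bbs_rho = unname(ct_b$estimate), bbs_p = ct_b$p.value,
               wilcoxon_w = unname(wt$statistic), faller_p = wt$p.value,
               note = "")
  })
  features <- do.call(rbind, rows)

  arm_tests <- list(
    sex = table(merged$arm, merged$sex),
    faller = table(merged$arm, faller)
  )
  arm <- do.call(rbind, lapply(names(arm_tests), function(nm) {
    tab <- arm_tests[[nm]]
    if (any(dim(tab) < 2)) {
      return(data.frame(variable = nm, chisq = NA, p = NA))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(variable = nm, chisq = unname(ct$statistic),
               p = ct$p.value)
  }))

  list(features = features, arm = arm)
}

#' Intra-session reliability: ICC(2,k)
#'
#' Two-way random-effects, absolute-agreement intraclass correlation for the
#' average of k repeated measurements, computed from the two-way ANOVA mean
#' squares:
#' \deqn{ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the between-subject,
#' between-trial and residual mean squares. The 95% confidence interval uses
#' the Shrout-Fleiss F-distribution method (single-rater bounds stepped up by
#' the Spearman-Brown relation). Reliability bands follow the conventional
#' cut-points: above 0.9 excellent, above 0.75 good, 0.5-0.75 moderate,
#' below 0.5 poor.
#'
#' @param trials_matrix numeric matrix, subjects x trials, of one feature.
#'   Rows with missing cells are dropped (the count is reported).
#' @param feature_name label carried into the result.
#' @param conf_level confidence level for the interval.
#' @return an object of class `icc_result`: list with `feature_name`, `icc`,
#'   `ci_low`, `ci_high`, `band`, `n_subjects`, `k_trials`, `n_dropped`.
#' @export
icc_2k <- function(trials_matrix, feature_name = "feature",
                   conf_level = 0.95) {
  m <- as.matrix(trials_matrix)
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) {
    stop("ICC(2,k) needs at least 3 complete subjects and 2 trials",
         call. = FALSE)
  }

  subj <- factor(rep(seq_len(n), k))
  trial <- factor(rep(seq_len(k), each = n))
  fit <- stats::aov(as.vector(m) ~ subj + trial)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]

  icc <- (msr - mse) / (msr + (msc - mse) / n)

  # Shrout-Fleiss interval for ICC(A,1), then Spearman-Brown step-up
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (icc1 >= 1 - 1e-12) {
    # perfect agreement: interval degenerates
    return(structure(
      list(feature_name = feature_name, icc = 1, ci_low = 1, ci_high = 1,
           band = "excellent", n_subjects = n, k_trials = k,
           n_dropped = n_dropped),
      class = "icc_result"
    ))
  }
  alpha <- 1 - conf_level
  a <- (k * icc1) / (n * (1 - icc1))
  b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  # Spearman-Brown step-up is monotone only above -1/(k-1); a single-rater
  # bound at or below that pole maps to an unbounded average-measures bound,
  # reported as -1
  sb <- function(r) {
    if (!is.finite(r) || 1 + (k - 1) * r <= 1e-12) return(-1)
    min(1, r * k / (1 + (k - 1) * r))
  }
  ci <- sort(c(sb(l1), sb(u1)))
  ci <- c(min(ci[1], icc), max(ci[2], icc))

  structure(
    list(feature_name = feature_name, icc = icc,
         ci_low = ci[1], ci_high = ci[2],
         band = icc_band(icc), n_subjects = n, k_trials = k,
         n_dropped = n_dropped),
    class = "icc_result"
  )
}

#' Reliability band for an ICC value
#'
#' Strictly greater than 0.9 is excellent, greater than 0.75 good, 0.5-0.75
#' moderate, below 0.5 poor.
#'
#' @param icc numeric ICC value(s).
#' @return character vector of bands.
#' @export
icc_band <- function(icc) {
  ifelse(icc > 0.9, "excellent",
         ifelse(icc > 0.75, "good",
                ifelse(icc >= 0.5, "moderate", "poor")))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> %s: ICC(2,%d) = %.3f [%.3f, %.3f] (%s; n = %d%s)\n",
    x$feature_name, x$k_trials, x$icc, x$ci_low, x$ci_high, x$band,
    x$n_subjects,
    if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""
  ))
  invisible(x)
}

#' Reliability table for a per-trial feature data.frame
#'
#' Reshapes trial-level features into subjects x trials matrices and applies
#' [icc_2k()] to every feature column.
#'
#' @param trial_features data.frame with `subject_id`, `trial_id` and numeric
#'   feature columns; every subject must have the same set of trial ids.
#' @return data.frame with one row per feature: icc, CI, band.
#' @export
reliability_table <- function(trial_features) {
  stopifnot(all(c("subject_id", "trial_id") %in% names(trial_features)))
  feat_cols <- setdiff(names(trial_features), c("subject_id", "trial_id"))
  do.call(rbind, lapply(feat_cols, function(f) {
    wide <- stats::reshape(
      trial_features[c("subject_id", "trial_id", f)],
      idvar = "subject_id", timevar = "trial_id", direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    res <- icc_2k(m, feature_name = f)
    data.frame(feature = f, icc = res$icc, ci_low = res$ci_low,
               ci_high = res$ci_high, band = res$band,
               n_subjects = res$n_subjects, n_dropped = res$n_dropped)
  }))
}
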