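#' Deterministic, optionally stratified cross-validation folds
#'
#' Fold assignment is a pure function of the number of rows, the seed and the
#' optional stratification labels, so every run with the same inputs gets
#' identical folds.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param seed integer seed.
#' @param strata optional label vector; folds are balanced within each level.
#' @return integer vector of fold ids in `1:k`.
#' @export
make_folds <- function(n, k, seed, strata = NULL) {
  stopifnot(k >= 2, n >= k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  folds <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (lv in unique(strata)) {
    idx <- which(strata == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Build a model design matrix from cohort and features
#'
#' Rows are subjects (the caller supplies one feature vector per subject —
#' first trial only for model fitting); columns are the named features plus
#' the demographic covariates age, sex (0 = male, 1 = female), height and
#' weight. Optionally all pairwise interactions among a candidate subset are
#' appended, with canonical names `"A:B"` (A before B lexicographically).
#' Constant columns are dropped with a warning; in sex-stratified matrices
#' the sex column disappears this way by construction.
#'
#' @param cohort validated cohort data.frame.
#' @param features data.frame or matrix of one row per subject (rownames or a
#'   `subject_id` column aligning with the cohort).
#' @param stratum `"pooled"`, `"male"` or `"female"`.
#' @param interactions logical; add pairwise interactions.
#' @param interaction_vars columns among which interactions are formed
#'   (default: all columns of the assembled matrix).
#' @return list of class `design_matrix` with elements `X` (numeric matrix),
#'   `subject_id`, `stratum`, `dropped` (names of constant columns removed).
#' @export
build_design_matrix <- function(cohort, features,
                                stratum = c("pooled", "male", "female"),
                                interactions = FALSE,
                                interaction_vars = NULL) {
  stratum <- match.arg(stratum)
  cohort <- validate_cohort(cohort)
  features <- as.data.frame(features)
  if ("subject_id" %in% names(features)) {
    rownames(features) <- features$subject_id
    features$subject_id <- NULL
  }
  if (all(cohort$subject_id %in% rownames(features))) {
    features <- features[cohort$subject_id, , drop = FALSE]
  } else if (nrow(features) == nrow(cohort)) {
    # unlabeled feature rows are taken in cohort order
    rownames(features) <- cohort$subject_id
  } else {
    stop("features must carry subject ids or match the cohort row count",
         call. = FALSE)
  }

  keep <- if (stratum == "pooled") rep(TRUE, nrow(cohort)) else cohort$sex == stratum
  cohort <- cohort[keep, , drop = FALSE]
  features <- features[keep, , drop = FALSE]

  X <- cbind(
    as.matrix(features),
    age = cohort$age,
    sex = as.numeric(cohort$sex == "female"),
    height = cohort$height_cm,
    weight = cohort$weight_kg
  )

  if (interactions) {
    vars <- interaction_vars %||% colnames(X)
    vars <- intersect(vars, colnames(X))
    if (length(vars) >= 2) {
      pairs <- utils::combn(sort(vars), 2)
      inter <- apply(pairs, 2, function(p) X[, p[1]] * X[, p[2]])
      colnames(inter) <- apply(pairs, 2, paste, collapse = ":")
      X <- cbind(X, inter)
    }
  }

  const <- apply(X, 2, function(col) stats::sd(col) < 1e-12)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }

  structure(
    list(X = X, subject_id = cohort$subject_id, stratum = stratum,
         dropped = names(const)[const]),
    class = "design_matrix"
  )
}

# z-standardize using training-row statistics only; returns the transformed
# full matrix (held-out rows scaled by the training parameters).
standardize_by_train <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sd <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  sd[sd < 1e-12] <- 1
  sweep(sweep(X, 2, mu), 2, sd, "/")
}

# Logistic fit by maximum likelihood (glm.fit); on non-convergence or
# quasi-separation, refit with a tiny ridge penalty (1e-6) via penalized
# IRLS, which keeps coefficients finite without altering the decision
# boundary materially.
fit_logistic <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial()))
  beta <- fit$coefficients
  if (!fit$converged || anyNA(beta) || max(abs(beta)) > 30) {
    beta <- ridge_logistic(Xi, y, lambda = 1e-6)
  }
  beta
}

ridge_logistic <- function(Xi, y, lambda = 1e-6, max_iter = 50) {
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- tryCatch(
      solve(crossprod(Xi, Xi * w) + pen, crossprod(Xi, w * z)),
      error = function(e) beta
    )
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

predict_logistic <- function(beta, X) {
  stats::plogis(drop(cbind(1, X) %*% beta))
}

# Sequential forward selection on one training set: greedily grow the model
# from the forced set, scoring candidates by inner cross-validated accuracy,
# until the best addition improves by less than `min_improve` (a proportion).
sfs_select <- function(X, y, forced, candidates, inner_folds = 5,
                       seed = 1, min_improve = 0.005, max_size = 15) {
  folds <- make_folds(length(y), inner_folds, seed, strata = y)
  cv_acc <- function(cols) {
    correct <- 0
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      beta <- fit_logistic(X[tr, cols, drop = FALSE], y[tr])
      pred <- predict_logistic(beta, X[!tr, cols, drop = FALSE]) >= 0.5
      correct <- correct + sum(pred == (y[!tr] == 1))
    }
    correct / length(y)
  }
  current <- forced
  best <- cv_acc(current)
  pool <- setdiff(candidates, forced)
  while (length(pool) && length(current) < max_size) {
    scores <- vapply(pool, function(cand) cv_acc(c(current, cand)), numeric(1))
    top <- which.max(scores)
    if (scores[top] - best < min_improve) break
    best <- scores[top]
    current <- c(current, pool[top])
    pool <- pool[-top]
  }
  current
}

#' Nested cross-validated logistic classification with forward selection
#'
#' For each outer fold, sequential forward selection is run on the training
#' subjects only (scored by inner cross-validated accuracy), starting from a
#' forced feature set — the time to complete the test is always included.
#' A maximum-likelihood logistic model on the selected features predicts the
#' held-out subjects at probability threshold 0.5; outer-fold predictions
#' are pooled into a single confusion matrix.
#'
#' @param X numeric design matrix (or a `design_matrix`), one row per subject.
#' @param y binary outcome (logical or 0/1).
#' @param k_folds outer folds (default 10), stratified on `y`.
#' @param forced column names always included (default `"total_time"`).
#' @param seed integer seed controlling all fold assignments.
#' @param inner_folds folds for the selection criterion.
#' @param min_improve_pp minimum accuracy improvement, percentage points, for
#'   a candidate to be added.
#' @param candidates candidate column names (default: all columns).
#' @param max_size maximum selected model size.
#' @return an object of class `classification_report`: pooled `metrics`
#'   (acc/sens/spec/ppv/npv, percent), `confusion`, `selected_features` per
#'   fold, `predictions`.
#' @export
sfs_logistic_cv <- function(X, y, k_folds = 10, forced = "total_time",
                            seed = 1, inner_folds = 5, min_improve_pp = 0.5,
                            candidates = NULL, max_size = 15) {
  if (inherits(X, "design_matrix")) X <- X$X
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), length(y) == nrow(X))
  if (min(table(y)) < k_folds) {
    stop("each class must have at least one subject per fold", call. = FALSE)
  }
  forced <- intersect(forced, colnames(X))
  candidates <- candidates %||% colnames(X)

  folds <- make_folds(length(y), k_folds, seed, strata = y)
  prob <- numeric(length(y))
  selected <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    Xs <- standardize_by_train(X, which(tr))
    sel <- sfs_select(Xs[tr, , drop = FALSE], y[tr], forced, candidates,
                      inner_folds = inner_folds, seed = seed + f,
                      min_improve = min_improve_pp / 100, max_size = max_size)
    beta <- fit_logistic(Xs[tr, sel, drop = FALSE], y[tr])
    prob[!tr] <- predict_logistic(beta, Xs[!tr, sel, drop = FALSE])
    selected[[f]] <- sel
  }
  pred <- as.integer(prob >= 0.5)
  conf <- c(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
            tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1))
  structure(
    list(metrics = classification_metrics(conf["tp"], conf["fp"],
                                          conf["tn"], conf["fn"]),
         confusion = conf, selected_features = selected,
         predictions = data.frame(fold = folds, prob = prob, pred = pred,
                                  obs = y),
         k_folds = k_folds, seed = seed),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<classification_report> %d-fold CV (n = %d)\n  Acc %.1f%%  Sens %.1f%%  Spec %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
    x$k_folds, nrow(x$predictions), m["acc"], m["sens"], m["spec"],
    m["ppv"], m["npv"]
  ))
  invisible(x)
}

#' Classification performance metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value, each as a percentage. A zero denominator yields `NA` rather than
#' NaN.
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return named numeric vector `acc, sens, spec, ppv, npv` (percent).
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  total <- tp + fp + tn + fn
  stopifnot(total >= 1)
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(acc = frac(tp + tn, total),
    sens = frac(tp, tp + fn),
    spec = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn))
}

#' Cross-validated elastic-net Poisson regression with size constraints
#'
#' Estimates a count-valued clinical score (MMSE or BBS) by penalized Poisson
#' regression. The elastic-net mixing parameter defaults to 0.1 (mostly
#' ridge, with enough lasso to produce sparse models). Within each outer
#' fold, the penalty strength is chosen by inner cross-validated deviance
#' among path solutions whose active-set size lies in `size_bounds`
#' (falling back to the nearest-size solution, with a warning, if none do).
#' The forced feature is excluded from the penalty, guaranteeing its
#' inclusion in every model. Held-out predictions through the log link are
#' pooled before computing metrics.
#'
#' @param X numeric design matrix or `design_matrix`.
#' @param y non-negative integer scores.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param size_bounds inclusive bounds on model size (number of features,
#'   intercept excluded), default `c(3, 20)`.
#' @param k_folds outer folds.
#' @param forced unpenalized, always-included column names.
#' @param seed integer seed.
#' @param inner_folds folds for the penalty-strength choice.
#' @return an object of class `regression_report`: `metrics` (r2, rmse,
#'   rho), `dof` (median selected size), `dof_per_fold`,
#'   `selected_features` per fold, `predictions`, `coefficients` (full-data
#'   refit at the constrained optimal penalty).
#' @export
poisson_elastic_net_cv <- function(X, y, alpha = 0.1, size_bounds = c(3, 20),
                                   k_folds = 10, forced = "total_time",
                                   seed = 1, inner_folds = 10) {
  if (inherits(X, "design_matrix")) X <- X$X
  stopifnot(length(y) == nrow(X), all(y >= 0))
  forced <- intersect(forced, colnames(X))
  pf <- rep(1, ncol(X))
  pf[colnames(X) %in% forced] <- 0

  fit_constrained <- function(Xtr, ytr, inner_seed) {
    foldid <- make_folds(length(ytr), inner_folds, inner_seed)
    cvfit <- glmnet::cv.glmnet(Xtr, ytr, family = "poisson", alpha = alpha,
                               penalty.factor = pf, foldid = foldid,
                               type.measure = "deviance")
    nz <- cvfit$nzero
    ok <- nz >= size_bounds[1] & nz <= size_bounds[2]
    if (any(ok)) {
      i <- which(ok)[which.min(cvfit$cvm[ok])]
    } else {
      warning("no path solution within size bounds; using nearest size",
              call. = FALSE)
      gap <- pmax(size_bounds[1] - nz, nz - size_bounds[2], 0)
      near <- which(gap == min(gap))
      i <- near[which.min(cvfit$cvm[near])]
    }
    list(cvfit = cvfit, lambda = cvfit$lambda[i], dof = unname(nz[i]))
  }

  folds <- make_folds(length(y), k_folds, seed)
  pred <- numeric(length(y))
  dof <- integer(k_folds)
  selected <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- fit_constrained(X[tr, , drop = FALSE], y[tr], seed + f)
    pred[!tr] <- as.numeric(
      stats::predict(fit$cvfit, X[!tr, , drop = FALSE], s = fit$lambda,
                     type = "response"))
    dof[f] <- fit$dof
    cf <- stats::coef(fit$cvfit, s = fit$lambda)
    selected[[f]] <- rownames(cf)[-1][as.numeric(cf)[-1] != 0]
  }

  full <- fit_constrained(X, y, seed)
  cf_full <- stats::coef(full$cvfit, s = full$lambda)

  structure(
    list(metrics = regression_metrics(y, pred),
         dof = stats::median(dof), dof_per_fold = dof,
         selected_features = selected,
         predictions = data.frame(fold = folds, pred = pred, obs = y),
         coefficients = stats::setNames(as.numeric(cf_full), rownames(cf_full)),
         alpha = alpha, size_bounds = size_bounds, k_folds = k_folds,
         seed = seed),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<regression_report> %d-fold CV (n = %d)\n  R2 %.3f  RMSE %.2f  rho %.3f  DoF %g\n",
    x$k_folds, nrow(x$predictions), m["r2"], m["rmse"], m["rho"], x$dof
  ))
  invisible(x)
}

#' Regression performance metrics on pooled predictions
#'
#' Coefficient of determination (1 - SS_res/SS_tot), root mean squared error
#' in score points, and Spearman's rank correlation.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 3).
#' @return named numeric vector `r2, rmse, rho`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y_true - y_pred)^2) / ss_tot else NA_real_
  rho <- if (ss_tot > 0 && stats::sd(y_pred) > 0) {
    suppressWarnings(stats::cor(y_true, y_pred, method = "spearman"))
  } else {
    NA_real_
  }
  c(r2 = r2,
    rmse = sqrt(mean((y_true - y_pred)^2)),
    rho = rho)
}

#' Average sex-stratified reports
#'
#' The "mean of sexes" summary is the unweighted mean of the male-model and
#' female-model metrics.
#'
#' @param male,female two metric vectors of equal names.
#' @return named numeric vector.
#' @export
mean_of_sexes <- function(male, female) {
  stopifnot(identical(names(male), names(female)))
  (male + female) / 2
}
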