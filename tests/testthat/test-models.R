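sim_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- c("total_time", paste0("f", seq_len(p - 1)))
  X
}

test_that("design matrices assemble mains, demographics and interactions", {
  cohort <- make_cohort(12, falls = rep(c(0, 2), 6))
  cohort$age <- 70:81
  cohort$height_cm <- seq(150, 183, 3)
  cohort$weight_kg <- seq(55, 88, 3)
  feats <- data.frame(subject_id = cohort$subject_id,
                      a_feat = rnorm(12), b_feat = rnorm(12),
                      total_time = rnorm(12) + 12)

  dm <- build_design_matrix(cohort, feats)
  expect_setequal(colnames(dm$X),
                  c("a_feat", "b_feat", "total_time", "age", "sex",
                    "height", "weight"))

  # three mains with interactions -> C(3,2) = 3 canonical pairwise columns
  dmi <- build_design_matrix(cohort, feats, interactions = TRUE,
                             interaction_vars = c("a_feat", "b_feat",
                                                  "total_time"))
  expect_true(all(c("a_feat:b_feat", "a_feat:total_time",
                    "b_feat:total_time") %in% colnames(dmi$X)))
  expect_equal(ncol(dmi$X), 7 + 3)
  expect_equal(dmi$X[, "a_feat:b_feat"], dmi$X[, "a_feat"] * dmi$X[, "b_feat"],
               ignore_attr = TRUE)

  # sex-stratified matrices drop the constant sex column
  expect_warning(
    dms <- build_design_matrix(cohort, feats, stratum = "female"),
    "sex"
  )
  expect_false("sex" %in% colnames(dms$X))
  expect_equal(nrow(dms$X), sum(cohort$sex == "female"))
})

test_that("standardization uses training rows only", {
  X <- sim_design(50, 4)
  tr <- 1:30
  Xs <- sitstand:::standardize_by_train(X, tr)
  expect_equal(unname(colMeans(Xs[tr, ])), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(Xs[tr, ], 2, sd)), rep(1, 4), tolerance = 1e-9)
  # held-out rows are scaled by the same parameters, not their own
  expect_gt(max(abs(colMeans(Xs[-tr, ]))), 1e-6)
})

test_that("classification metrics match hand arithmetic", {
  m <- classification_metrics(tp = 40, fn = 8, tn = 45, fp = 7)
  expect_equal(unname(m["acc"]), 85.0)
  expect_equal(unname(m["sens"]), 83.3, tolerance = 0.05)
  expect_equal(unname(m["spec"]), 86.5, tolerance = 0.05)

  perfect <- classification_metrics(10, 0, 10, 0)
  expect_equal(unname(perfect), rep(100, 5))

  allpos <- classification_metrics(tp = 50, fp = 50, tn = 0, fn = 0)
  expect_equal(unname(allpos["sens"]), 100)
  expect_equal(unname(allpos["spec"]), 0)
  expect_equal(unname(allpos["acc"]), 50)
  expect_true(is.na(allpos["npv"]))  # zero denominator -> not applicable
})

test_that("regression metrics match their definitions", {
  y <- c(50, 52, 54, 56)
  expect_equal(unname(regression_metrics(y, y)),
               c(1, 0, 1))
  m <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(unname(m["r2"]), 0)
  expect_equal(unname(regression_metrics(y, c(51, 53, 53, 57))["rmse"]), 1.0)
  expect_true(is.na(regression_metrics(rep(5, 4), c(1, 2, 3, 4))["r2"]))
})

test_that("fold assignment is a deterministic function of size and seed", {
  f1 <- make_folds(100, 10, seed = 3)
  f2 <- make_folds(100, 10, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(100, 10, seed = 4)))
  # stratified folds put both classes in every fold
  y <- rep(c(0, 1), c(60, 40))
  fs <- make_folds(100, 10, seed = 1, strata = y)
  tab <- table(fs, y)
  expect_true(all(tab > 0))
  # fold creation does not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_folds(50, 5, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the forced feature is selected in every fold", {
  X <- sim_design(120, 8, seed = 2)
  y <- rbinom(120, 1, plogis(1.5 * X[, "f3"]))
  rep <- sfs_logistic_cv(X, y, k_folds = 5, seed = 1)
  expect_true(all(vapply(rep$selected_features,
                         function(s) "total_time" %in% s, logical(1))))
})

test_that("informative features yield high cross-validated accuracy", {
  X <- sim_design(300, 12, seed = 3)
  eta <- 2 * X[, "f1"] + 2 * X[, "f5"]
  set.seed(4)
  y <- rbinom(300, 1, plogis(eta))
  rep <- sfs_logistic_cv(X, y, k_folds = 5, seed = 2)
  expect_gte(unname(rep$metrics["acc"]), 80)
  # the informative features dominate the selections
  hits <- mean(vapply(rep$selected_features,
                      function(s) all(c("f1", "f5") %in% s), logical(1)))
  expect_gte(hits, 0.8)
})

test_that("permuted labels stay near chance (no selection leakage)", {
  X <- sim_design(100, 10, seed = 5)
  accs <- vapply(1:3, function(r) {
    set.seed(100 + r)
    y <- sample(rep(c(0, 1), 50))
    unname(sfs_logistic_cv(X, y, k_folds = 5, seed = r)$metrics["acc"])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 12)
})

test_that("pooled metrics equal metrics from summed per-fold confusions", {
  X <- sim_design(120, 6, seed = 6)
  y <- rbinom(120, 1, plogis(X[, "f2"]))
  rep <- sfs_logistic_cv(X, y, k_folds = 6, seed = 3)
  pr <- rep$predictions
  conf <- rowSums(vapply(sort(unique(pr$fold)), function(f) {
    p <- pr[pr$fold == f, ]
    c(tp = sum(p$pred == 1 & p$obs == 1), fp = sum(p$pred == 1 & p$obs == 0),
      tn = sum(p$pred == 0 & p$obs == 0), fn = sum(p$pred == 0 & p$obs == 1))
  }, numeric(4)))
  expect_equal(unname(conf), unname(rep$confusion))
  expect_equal(classification_metrics(conf["tp"], conf["fp"],
                                      conf["tn"], conf["fn"]),
               rep$metrics)
})

test_that("ridge (alpha = 0) keeps every candidate in the model", {
  X <- sim_design(200, 8, seed = 7)
  set.seed(8)
  y <- rpois(200, exp(2 + 0.2 * X[, "f1"]))
  rep <- poisson_elastic_net_cv(X, y, alpha = 0, size_bounds = c(3, 20),
                                k_folds = 5, seed = 1)
  expect_equal(rep$dof, 8)
})

test_that("a noise-free log link is recovered almost exactly", {
  X <- sim_design(400, 8, seed = 9)
  beta <- c(total_time = -0.2, f1 = 0.3, f2 = -0.25)
  eta <- 2.5 + X[, names(beta)] %*% beta
  y <- round(exp(eta))
  rep <- poisson_elastic_net_cv(X, y, k_folds = 5, seed = 2)
  expect_gte(unname(rep$metrics["r2"]), 0.95)
  expect_true(all(rep$dof_per_fold >= 3 & rep$dof_per_fold <= 20))
})

test_that("vanishing penalty converges to the unpenalized Poisson MLE", {
  X <- sim_design(500, 4, seed = 10)
  set.seed(11)
  y <- rpois(500, exp(1 + 0.3 * X[, "f1"] - 0.2 * X[, "f2"]))
  mle <- glm(y ~ X, family = poisson())
  en <- glmnet::glmnet(X, y, family = "poisson", alpha = 0.1,
                       lambda = c(0.1, 0.01, 1e-7))
  cf <- as.numeric(coef(en, s = 1e-7))
  expect_equal(cf, unname(coef(mle)), tolerance = 1e-3)
})

test_that("held-out subjects cannot influence their own fold's selection", {
  set.seed(12)
  X <- sim_design(110, 6, seed = 12)
  y <- rbinom(110, 1, plogis(X[, "f1"]))
  folds <- make_folds(110, 5, seed = 7, strata = y)

  rep1 <- sfs_logistic_cv(X, y, k_folds = 5, seed = 7)
  # corrupt the feature values of fold-1's held-out subjects; fold 1's
  # training data (and hence its standardization and selection) is untouched
  X2 <- X
  X2[folds == 1, -1] <- X2[folds == 1, -1] * 100 + 57
  rep2 <- sfs_logistic_cv(X2, y, k_folds = 5, seed = 7)
  expect_identical(rep1$selected_features[[1]], rep2$selected_features[[1]])
})
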