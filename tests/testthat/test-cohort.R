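test_that("faller labeling follows the falls-history definition exactly", {
  expect_true(label_faller(2, FALSE))   # more than one fall
  expect_true(label_faller(1, TRUE))    # one injurious fall
  expect_false(label_faller(1, FALSE))  # one non-injurious fall
  expect_false(label_faller(0, FALSE))
  # injury without any recorded fall does not make a faller
  expect_false(label_faller(0, TRUE))
  expect_equal(label_faller(c(0, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE)),
               c(FALSE, TRUE, TRUE, TRUE))
})

test_that("score dichotomization uses the 27 and 53 cut-offs", {
  d <- dichotomize_scores(mmse = c(26, 27, 30), bbs = c(52, 53, 56))
  expect_equal(d$cognitive_impaired, c(TRUE, FALSE, FALSE))
  expect_equal(d$balance_impaired, c(TRUE, FALSE, FALSE))
})

test_that("a feature monotone in MMSE gives Spearman rho of 1", {
  n <- 20
  cohort <- make_cohort(n, mmse = round(seq(10, 29, length.out = n)),
                        falls = rep(c(0, 2), each = n / 2))
  feats <- data.frame(subject_id = cohort$subject_id,
                      trial_id = "T1",
                      f_mono = exp(seq(10, 29, length.out = n) / 5),
                      f_const = 1)
  res <- association_tests(cohort, feats)
  row <- res$features[res$features$feature == "f_mono", ]
  expect_equal(row$mmse_rho, 1.0)
  # constant features report NA with a note, never NaN
  crow <- res$features[res$features$feature == "f_const", ]
  expect_true(is.na(crow$mmse_rho))
  expect_equal(crow$note, "constant feature")
})

test_that("Spearman rho is invariant under monotone transforms", {
  n <- 24
  set.seed(8)
  mmse <- sample(20:30, n, replace = TRUE)
  x <- rnorm(n) + mmse / 5
  cohort <- make_cohort(n, mmse = mmse, falls = rep(c(0, 2), each = n / 2))
  f1 <- data.frame(subject_id = cohort$subject_id, trial_id = "T1", f = x)
  f2 <- data.frame(subject_id = cohort$subject_id, trial_id = "T1",
                   f = exp(3 * x))
  r1 <- association_tests(cohort, f1)$features$mmse_rho
  r2 <- association_tests(cohort, f2)$features$mmse_rho
  expect_equal(r1, r2)
})

test_that("identical faller and non-faller samples give Wilcoxon p near 1", {
  n <- 20
  vals <- rep(seq_len(n / 2), 2)
  cohort <- make_cohort(n, falls = rep(c(0, 2), each = n / 2))
  feats <- data.frame(subject_id = cohort$subject_id, trial_id = "T1",
                      f = vals[order(rep(c(1, 2), each = n / 2))])
  # arrange so both groups hold exactly the same multiset of values
  feats$f <- c(seq_len(n / 2), seq_len(n / 2))
  res <- association_tests(cohort, feats)
  expect_gte(res$features$faller_p, 0.99)
})

test_that("equal proportions between arms give a chi-square statistic of 0", {
  n <- 90
  cohort <- make_cohort(
    n,
    sex = c(rep(c("male", "female"), c(30, 30)),
            rep(c("male", "female"), c(15, 15))),
    arm = rep(c("home", "clinic"), c(60, 30)),
    falls = rep(c(0, 2), length.out = n)
  )
  feats <- data.frame(subject_id = cohort$subject_id, trial_id = "T1",
                      f = seq_len(n))
  res <- association_tests(cohort, feats)
  sex_row <- res$arm[res$arm$variable == "sex", ]
  expect_equal(sex_row$chisq, 0, tolerance = 1e-12)
})

test_that("features are averaged per subject before testing", {
  n <- 10
  cohort <- make_cohort(n, mmse = 21:30, falls = rep(c(0, 2), each = 5))
  # two trials whose average is monotone in MMSE even though single trials
  # are not
  feats <- rbind(
    data.frame(subject_id = cohort$subject_id, trial_id = "T1",
               f = (21:30) + 5),
    data.frame(subject_id = cohort$subject_id, trial_id = "T2",
               f = (21:30) - 5)
  )
  res <- association_tests(cohort, feats)
  expect_equal(res$features$mmse_rho, 1.0)
})

test_that("ICC(2,k) matches an explicit-sum ANOVA oracle to 1e-10", {
  set.seed(7)
  for (rep_i in 1:50) {
    n <- sample(5:30, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n, sd = runif(1, 0, 2))  # row effects
    res <- icc_2k(m)
    expect_equal(res$icc, icc_oracle(m), tolerance = 1e-10)
    expect_lte(res$ci_low, res$icc + 1e-12)
    expect_gte(res$ci_high, res$icc - 1e-12)
  }
})

test_that("identical trial columns give perfect reliability", {
  v <- rnorm(12)
  res <- icc_2k(cbind(v, v, v))
  expect_equal(res$icc, 1.0)
  expect_equal(res$band, "excellent")
})

test_that("reliability bands honor the 0.5/0.75/0.9 cut-points", {
  expect_equal(icc_band(0.91), "excellent")
  expect_equal(icc_band(0.90), "good")      # strictly greater than 0.9
  expect_equal(icc_band(0.76), "good")
  expect_equal(icc_band(0.75), "moderate")  # strictly greater than 0.75
  expect_equal(icc_band(0.50), "moderate")
  expect_equal(icc_band(0.49), "poor")
})

test_that("ICC is invariant to shifts and positive rescaling", {
  set.seed(11)
  m <- matrix(rnorm(45), 15, 3) + rnorm(15)
  base <- icc_2k(m)$icc
  expect_equal(icc_2k(m + 100)$icc, base, tolerance = 1e-10)
  expect_equal(icc_2k(m * 7.3)$icc, base, tolerance = 1e-10)
})

test_that("degenerate and undersized inputs are handled", {
  # zero between-subject variance: icc <= 0, poor band
  set.seed(2)
  m <- matrix(rnorm(60, mean = 5), 20, 3)
  res <- icc_2k(m)
  expect_lte(res$icc, 0.3)
  # too small
  expect_error(icc_2k(matrix(rnorm(4), 2, 2)), "at least 3")
  # missing cells are dropped and counted
  m[3, 2] <- NA
  res2 <- icc_2k(m)
  expect_equal(res2$n_dropped, 1)
  expect_equal(res2$n_subjects, 19)
})

test_that("cohort validation catches malformed tables", {
  bad <- make_cohort(5)
  bad$mmse[1] <- 31
  expect_error(sitstand:::validate_cohort(bad), "mmse")
  bad2 <- make_cohort(5)
  bad2$bbs[2] <- 60
  expect_error(sitstand:::validate_cohort(bad2), "bbs")
})
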