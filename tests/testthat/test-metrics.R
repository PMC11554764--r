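test_that("AUC handles separation, ties, and mixed orderings", {
  expect_equal(auc(c(1, 2), c(3, 4)), 1)          # low scores = impaired
  expect_equal(auc(c(5, 5, 5), c(5, 5)), 0.5)     # ties only
  expect_equal(auc(c(1, 3), c(2, 4)), 0.75)       # 3 of 4 pairs correct
  expect_equal(auc(c(3, 4), c(1, 2)), 0)
  expect_error(auc(numeric(0), c(1)), "non-empty")
})

test_that("rank-based AUC equals the brute-force all-pairs statistic", {
  set.seed(31)
  for (i in 1:25) {
    n_pos <- sample(1:200, 1)
    n_neg <- sample(1:200, 1)
    # rounding induces ties in roughly half the instances
    pos <- rnorm(n_pos, 20, 4)
    neg <- rnorm(n_neg, 24, 4)
    if (i %% 2 == 0) {
      pos <- round(pos)
      neg <- round(neg)
    }
    expect_equal(auc(pos, neg), auc_bruteforce(pos, neg))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(32)
  pos <- rnorm(80, 18, 3)
  neg <- rnorm(120, 24, 3)
  expect_equal(auc(exp(pos / 10), exp(neg / 10)), auc(pos, neg))
  expect_equal(auc(pos^3, neg^3), auc(pos, neg))
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(33)
  pos <- round(rnorm(150, 19, 4))
  neg <- round(rnorm(250, 24, 3))
  ref <- pROC::roc(response = c(rep(1, length(pos)), rep(0, length(neg))),
                   predictor = c(pos, neg), direction = ">",
                   levels = c(0, 1), quiet = TRUE)
  expect_equal(auc(pos, neg), as.numeric(ref$auc))
})

test_that("specificity cutoff is the interpolated healthy quantile", {
  healthy <- 1:1000
  c90 <- find_cutoff_specificity(healthy, 0.90)
  expect_equal(c90, 100.9)
  expect_equal(sum(healthy >= c90), 900)
  # brute-force check: no threshold with specificity >= 0.90 admits more
  # positives than the returned one
  expect_equal(mean(healthy >= c90), 0.90, tolerance = 1 / length(healthy))

  # near-1 target: cutoff at or below the minimum, specificity 1
  expect_lte(find_cutoff_specificity(healthy, 1 - 1e-9), min(healthy) + 1e-5)

  set.seed(34)
  cont <- rnorm(5000, 24, 3)
  cut <- find_cutoff_specificity(cont, 0.977)
  expect_equal(mean(cont >= cut), 0.977, tolerance = 1 / length(cont))

  expect_error(find_cutoff_specificity(cont, 0), "between 0 and 1")
  expect_error(find_cutoff_specificity(cont, 1.2), "between 0 and 1")
  expect_error(find_cutoff_specificity(numeric(0), 0.9), "no healthy")
})

test_that("sensitivity cutoff is the interpolated MCI quantile", {
  mci <- 1:1000
  c90 <- find_cutoff_sensitivity(mci, 0.90)
  expect_equal(sum(mci < c90), 900)
  expect_lte(find_cutoff_sensitivity(mci, 1e-9), min(mci) + 1e-5)
  set.seed(35)
  cont <- rnorm(3000, 19, 3)
  cut <- find_cutoff_sensitivity(cont, 0.841)
  expect_equal(mean(cont < cut), 0.841, tolerance = 1 / length(cont))
  expect_error(find_cutoff_sensitivity(cont, 1), "between 0 and 1")
})

test_that("sensitivity and specificity count correctly on a toy cohort", {
  toy <- make_cohort(age = c(60, 60, 60, 60), edu_years = 8,
                     status = c("MCI", "MCI", "healthy", "healthy"),
                     raw_score = c(10, 20, 25, 28))
  ss <- sens_spec(toy, "raw", cutoff = 22, stratified = FALSE)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)

  # scores equal to the cutoff screen negative
  ss2 <- sens_spec(toy, "raw", cutoff = 20, stratified = FALSE)
  expect_equal(ss2$sensitivity, 0.5)

  # cutoff below every score: nobody screens positive
  ss3 <- sens_spec(toy, "raw", cutoff = 5, stratified = FALSE)
  expect_equal(ss3$sensitivity, 0)
  expect_equal(ss3$specificity, 1)

  expect_error(sens_spec(toy, "corrected", 22), "no corrected_score")
  only_mci <- make_cohort(age = 60, edu_years = 8, status = "MCI",
                          raw_score = 10)
  expect_error(sens_spec(only_mci, "raw", 22), "both MCI and healthy")
})

test_that("dementia cases are excluded from sensitivity/specificity", {
  toy <- make_cohort(age = rep(70, 5), edu_years = 8,
                     status = c("MCI", "healthy", "dementia", "dementia",
                                "dementia"),
                     raw_score = c(10, 28, 1, 2, 3))
  ss <- sens_spec(toy, "raw", cutoff = 22, stratified = FALSE)
  expect_equal(ss$n_mci, 1L)
  expect_equal(ss$n_healthy, 1L)
  expect_equal(ss$sensitivity, 1)
})

test_that("marginal metrics are the weighted averages of stratum metrics", {
  tab <- load_joint_table()
  set.seed(36)
  cohort <- sample_cohort(tab, 20000)
  cohort <- generate_raw_scores(cohort, normative_equation("aiello"),
                                score_gen_params())
  cut <- find_cutoff_specificity(
    cohort$raw_score[cohort$status == "healthy"], 0.841)
  ss <- sens_spec(cohort, "raw", cut, stratified = TRUE)
  st <- ss$strata
  expect_equal(nrow(st), 35L)
  defined_se <- !is.na(st$sensitivity)
  expect_equal(sum(st$n_mci[defined_se] * st$sensitivity[defined_se]) /
                 sum(st$n_mci[defined_se]),
               ss$sensitivity, tolerance = 1e-12)
  defined_sp <- !is.na(st$specificity)
  expect_equal(sum(st$n_healthy[defined_sp] * st$specificity[defined_sp]) /
                 sum(st$n_healthy[defined_sp]),
               ss$specificity, tolerance = 1e-12)
  # empty-class strata are flagged as undefined, not zero
  expect_true(all(is.na(st$sensitivity[st$n_mci == 0])))
})

test_that("per-stratum cutoffs equalize raw and corrected performance", {
  # with a constant age inside each stratum the correction is a constant
  # shift per stratum, so stratum-specific quantile cutoffs must give
  # bit-identical sensitivity and specificity for raw and corrected scores
  tab <- load_joint_table()
  eq <- normative_equation("aiello")
  set.seed(37)
  dev <- sample_cohort(tab, 5000)
  dev$age <- as.numeric(sub("-.*", "", as.character(dev$age_group))) + 2.5
  dev <- generate_raw_scores(dev, eq, score_gen_params())
  val <- sample_cohort(tab, 20000)
  val$age <- as.numeric(sub("-.*", "", as.character(val$age_group))) + 2.5
  val <- generate_raw_scores(val, eq, score_gen_params())
  fit <- fit_normative(dev, eq)
  dev <- apply_correction(dev, fit)
  val <- apply_correction(val, fit)

  key_dev <- interaction(dev$age_group, dev$edu_years, drop = FALSE)
  key_val <- interaction(val$age_group, val$edu_years, drop = FALSE)
  for (stratum in levels(key_val)) {
    d <- dev[key_dev == stratum & dev$status == "healthy", ]
    v <- val[key_val == stratum, ]
    if (nrow(d) < 2 || !any(v$status == "MCI") || !any(v$status == "healthy"))
      next
    cut_raw <- find_cutoff_specificity(d$raw_score, 0.841)
    cut_cor <- find_cutoff_specificity(d$corrected_score, 0.841)
    ss_raw <- sens_spec(v, "raw", cut_raw, stratified = FALSE)
    ss_cor <- sens_spec(v, "corrected", cut_cor, stratified = FALSE)
    expect_equal(ss_cor$sensitivity, ss_raw$sensitivity)
    expect_equal(ss_cor$specificity, ss_raw$specificity)
  }
})
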