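test_that("two-sample t tests behave at the edges", {
  expect_equal(t_test2(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  expect_equal(t_test2(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  deg <- t_test2(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # permutation sanity: under label shuffling, small p values occur at
  # their nominal rate
  set.seed(21)
  pooled <- rnorm(30)
  ps <- replicate(400, {
    idx <- sample(30, 14)
    t_test2(pooled[idx], pooled[-idx])$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_gt(mean(ps), 0.35)
})

test_that("summary-statistic t test equals the raw-data test", {
  expect_equal(t_test_from_summary(5, 1, 10, 5, 2, 12)$p_value, 1.0)
  set.seed(3)
  x0 <- moment_match(rnorm(36), 3.47, 1.79)
  x1 <- moment_match(rnorm(24), 5.23, 1.79)
  for (variant in c("student_pooled", "welch")) {
    raw <- t_test2(x0, x1, variant)
    summ <- t_test_from_summary(3.47, 1.79, 36, 5.23, 1.79, 24, variant)
    expect_equal(summ$p_value, raw$p_value, tolerance = 1e-12)
    expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
  }
  # threshold-segmentation fully corrected SUR_MAX group moments:
  # Welch t ~ 3.57, p in the 0.0005-0.001 band
  w <- t_test_from_summary(3.43, 1.75, 36, 5.06, 1.72, 24, "welch")
  expect_equal(w$statistic, 3.57, tolerance = 0.005)
  expect_gt(w$p_value, 0.0005)
  expect_lt(w$p_value, 0.001)
})

test_that("rank-sum test approximates the exact permutation null", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  deg <- wilcoxon_rank_sum(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # fully separated 3-vs-3: exact enumeration gives 2/20 = 0.1; the
  # continuity-corrected normal approximation lands within its known error
  p_exact <- exact_wilcoxon_p(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_exact, 0.1)
  p_norm <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value
  expect_lt(abs(p_norm - p_exact), 0.05)
  # rank statistic is invariant under strictly monotone transforms
  set.seed(4)
  a <- rnorm(15)
  b <- rnorm(12, 1)
  expect_equal(wilcoxon_rank_sum(exp(a), exp(b))$p_value,
               wilcoxon_rank_sum(a, b)$p_value)
  # the t test is not (behavioral contrast, regression-locked)
  expect_false(isTRUE(all.equal(t_test2(exp(a), exp(b))$p_value,
                                t_test2(a, b)$p_value)))
})

test_that("empirical ROC and AUC follow the Mann-Whitney relation", {
  expect_equal(roc(c(1, 2, 3), c(4, 5, 6))$auc, 1.0)
  expect_equal(roc(c(1, 3), c(2, 4))$auc, 0.75)  # 3 of 4 pairs concordant
  expect_equal(roc(c(1, 2), c(1, 2))$auc, 0.5)   # ties count one half
  # complement symmetry for tie-free data
  set.seed(6)
  a <- rnorm(20)
  b <- rnorm(25, 0.4)
  expect_equal(roc(a, b)$auc + roc(b, a)$auc, 1.0)
  # monotone-transform invariance
  expect_equal(roc(exp(a), exp(b))$auc, roc(a, b)$auc)
  # curve endpoints
  cv <- roc(a, b)$curve
  expect_equal(cv$tpr[1], 1)
  expect_equal(cv$fpr[1], 1)
  expect_equal(cv$tpr[nrow(cv)], 0)
  expect_equal(cv$fpr[nrow(cv)], 0)
})

test_that("empirical AUC converges to the binormal value", {
  set.seed(8)
  n <- 6000
  mu0 <- 3.43; sd0 <- 1.75; mu1 <- 5.06; sd1 <- 1.72
  a <- rnorm(n, mu0, sd0)
  b <- rnorm(n, mu1, sd1)
  expected <- pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
  expect_equal(roc(a, b)$auc, expected, tolerance = 0.01 / expected)
})

test_that("logistic fit matches a direct ML oracle and Youden cutoffs", {
  # fully separated groups: sens = spec = 1, non-convergence flagged
  lc <- logistic_cutoff(c(1, 2, 3), c(4, 5, 6))
  expect_false(lc$converged)
  expect_equal(lc$sensitivity, 1)
  expect_equal(lc$specificity, 1)
  expect_gt(lc$cutoff, 3)
  expect_lte(lc$cutoff, 4)
  # overlapping fixed dataset: coefficients agree with Nelder-Mead ML
  x0 <- c(1.2, 2.1, 2.7, 3.3, 4.0, 4.8, 2.4, 3.9)
  x1 <- c(2.9, 3.6, 4.4, 5.1, 5.9, 4.2, 6.3, 3.1)
  lc2 <- logistic_cutoff(x0, x1)
  expect_true(lc2$converged)
  oracle <- logistic_ml_oracle(c(x0, x1),
                               rep(c(0, 1), c(length(x0), length(x1))))
  expect_equal(unname(lc2$coefficients), oracle, tolerance = 1e-4)
  expect_equal(lc2$p50_crossing,
               -lc2$coefficients[["intercept"]] /
                 lc2$coefficients[["slope"]])
  # symmetric groups put the cutoff near zero
  set.seed(10)
  s0 <- rnorm(300, -1)
  s1 <- rnorm(300, 1)
  expect_lt(abs(logistic_cutoff(s0, s1)$cutoff), 0.35)
  # reported sens/spec realize the maximal Youden index
  cv <- roc(x0, x1)$curve
  cv <- cv[is.finite(cv$threshold), ]
  expect_equal(lc2$youden, max(cv$tpr - cv$fpr))
})

test_that("results grid covers all families and flags bad subsets", {
  set.seed(12)
  curves <- test_rc_curves()
  cohort <- generate_forward_model(
    cohort_params(n_wt = 20, n_mut = 20,
                  true_suv0_wt = c(6, 1.5), true_suv0_mut = c(6, 1.5)),
    curves, noise_sd = 0.05, seed = 13
  )
  cohort$segmentation <- "sim"
  corrected <- suppressWarnings(
    correct_cohort(cohort, curves, peak_voi_ml = NULL))
  grid <- build_results_grid(corrected)
  expect_equal(nrow(grid), 18L)  # 6 families x 3 statistics x 1 tag
  expect_true(all(grid$auc >= 0 & grid$auc <= 1))
  expect_true(all(grid$t_p > 0 & grid$t_p <= 1))
  # identical group-generating distributions: no real separation
  expect_true(all(grid$auc > 0.25 & grid$auc < 0.75))
  expect_gt(median(grid$t_p), 0.05)
  # deterministic given the cohort
  expect_identical(grid, build_results_grid(corrected))
  # subset filters fail loudly
  expect_error(build_results_grid(corrected,
                                  exclude_treated_vicinity = TRUE),
               "treated_vicinity")
  corrected$treated_vicinity <- TRUE
  expect_error(build_results_grid(corrected,
                                  exclude_treated_vicinity = TRUE),
               "no lesions left")
  expect_error(build_results_grid(corrected, families = "nope"),
               "nope_mean")
})

test_that("separated summary-matched groups yield the expected grid row", {
  coh <- generate_summary_matched(cohort_params(), "sur_pvec_time",
                                  "hermes", seed = 19)
  grid <- build_results_grid(coh, families = "sur_pvec_time")
  expect_equal(nrow(grid), 3L)
  row_max <- grid[grid$statistic == "max", ]
  expect_lt(row_max$t_p, 0.05)
  expect_gt(row_max$auc, 0.6)
  expect_true(row_max$sensitivity >= 0 & row_max$sensitivity <= 1)
})
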