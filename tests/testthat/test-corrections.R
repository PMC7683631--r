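test_that("partial-volume correction inverts the attenuation model", {
  # worked examples
  expect_equal(pvec(6.0, 1.0, 2.4), 6.0)
  expect_equal(pvec(6.0, 0.8, 2.4), 6.9)   # 6/0.8 - 2.4 * 0.25
  expect_equal(pvec(6.0, 0.5, 0.0), 12.0)
  expect_error(pvec(6.0, 0, 2.4), "positive")
  expect_error(pvec(6.0, -0.2, 2.4), "positive")
  expect_warning(pvec(1.0, 0.1, 5.0), "background exceeds")
  # exact inverse of measured = rc * true + (1 - rc) * bg
  set.seed(11)
  true <- runif(500, 1, 20)
  rc <- runif(500, 0.2, 1.2)
  bg <- runif(500, 0, 4)
  measured <- rc * true + (1 - rc) * bg
  expect_equal(pvec(measured, rc, bg), true, tolerance = 1e-12)
  # correction never shrinks the signal when rc <= 1 and suv >= bg
  keep <- rc <= 1 & measured >= bg
  expect_true(all(pvec(measured[keep], rc[keep], bg[keep]) >=
                    measured[keep] - 1e-12))
})

test_that("uptake ratios are simple, guarded and calibration-invariant", {
  expect_equal(suvtlr(6.0, 2.7), 6.0 / 2.7)
  expect_equal(round(suvtlr(6.0, 2.7), 1), 2.2)
  expect_equal(suvtlr(3.3, 3.3), 1.0)
  expect_equal(suvtlr(0, 2.7), 0)
  expect_error(suvtlr(6, 0), "positive")
  expect_equal(sur(5.0, 2.0), 2.5)
  expect_equal(sur(2.0, 2.0), 1.0)
  expect_equal(sur(5.0 * 1.37, 2.0 * 1.37), sur(5.0, 2.0))
  expect_error(sur(5, 0), "positive")
})

test_that("SUR time correction has the right fixed points and values", {
  p <- uptake_params()
  expect_equal(p$t0_min, 60)
  expect_equal(p$vr, 0.53)
  expect_equal(p$b, 0.313)
  # identity at the standard time, both modes
  expect_equal(time_correct_sur(3.7, 60, p, "exact"), 3.7)
  expect_equal(time_correct_sur(3.7, 60, p, "approx"), 3.7)
  # the apparent volume of distribution is a fixed point of the exact form
  expect_equal(time_correct_sur(0.53, 137, p, "exact"), 0.53)
  # hand-evaluated example at T = 120
  expect_equal(time_correct_sur(4.0, 120, p, "exact"),
               0.5 * (4 - 0.53) + 0.53)  # 2.265
  expect_equal(time_correct_sur(4.0, 120, p, "approx"), 2.0)
  expect_error(time_correct_sur(4.0, 0, p), "positive")
})

test_that("SUV time correction follows the power law", {
  p <- uptake_params()
  expect_equal(time_correct_suv(8.0, 60, p, "approx"), 8.0)
  expect_equal(time_correct_suv(8.0, 120, p, "approx"),
               8 * 0.5^0.687, tolerance = 1e-12)
  expect_equal(8 * 0.5^0.687, 4.969, tolerance = 1e-4)
  # monotone decreasing in T (exponent 1 - b > 0)
  ts <- seq(45, 200, by = 5)
  expect_true(all(diff(time_correct_suv(8.0, ts, p, "approx")) < 0))
  # exact mode needs and checks the tumor-to-blood ratio
  expect_error(time_correct_suv(8.0, 90, p, "exact"), "sur_t")
  expect_error(time_correct_suv(8.0, 90, p, "exact", sur_t = 0), "positive")
  expect_equal(time_correct_suv(8.0, 60, p, "exact", sur_t = 4.0), 8.0)
})

test_that("approximate SUR correction drifts from the exact form with |T - T0|", {
  # the two forms differ by Vr (T0/T - 1), relative to the exact value:
  # exact agreement at T0, a few percent nearby, and growing toward the
  # extremes of the observed 40-206 min uptake range (regression-locked)
  p <- uptake_params()
  rel_err <- function(s, ts) {
    abs(time_correct_sur(s, ts, p, "approx") /
          time_correct_sur(s, ts, p, "exact") - 1)
  }
  expect_equal(rel_err(3, 60), 0)
  for (s in c(2, 3, 5, 8)) {
    expect_lt(max(rel_err(s, seq(48, 75, by = 1))), 0.08)
  }
  # analytic form of the disagreement
  ts <- seq(40, 206, by = 2)
  s <- 4
  expect_equal(rel_err(s, ts),
               abs(p$vr * (p$t0_min / ts - 1)) /
                 time_correct_sur(s, ts, p, "exact"),
               tolerance = 1e-12)
  # at the long-uptake end the discrepancy is large, not bounded by 8%
  expect_gt(rel_err(2, 206), 0.3)
})

test_that("peak fallback substitutes the mean for sub-VOI lesions", {
  df <- data.frame(volume_mL = c(0.3, 5), suv_mean = c(4, 6),
                   suv_peak = c(9, 7), suv_max = c(10, 9))
  out <- peak_fallback(df, 1.0)
  expect_equal(out$suv_peak, c(4, 7))
  expect_equal(out$peak_substituted, c(TRUE, FALSE))
})

make_lesions <- function(n = 8, seed = 5) {
  set.seed(seed)
  data.frame(
    lesion_id = seq_len(n),
    volume_mL = exp(runif(n, log(1.2), log(30))),
    suv_mean = runif(n, 4, 9),
    suv_peak = runif(n, 5, 10),
    suv_max = runif(n, 6, 13),
    suv_bg_local = runif(n, 1.8, 3),
    suv_liver_mean = runif(n, 2.2, 3.2),
    suv_blood_mean = runif(n, 1.6, 2.8),
    uptake_time_min = runif(n, 45, 180)
  )
}

test_that("correction chain collapses to raw metrics when switched off", {
  les <- make_lesions()
  curves <- test_rc_curves()
  # corrections disabled
  off <- correct_cohort(les, curves, apply_pvec = FALSE, apply_time = FALSE)
  expect_equal(off$suv_pvec_mean, les$suv_mean)
  expect_equal(off$suv_pvec_time_max, les$suv_max)
  expect_equal(off$sur_time_mean, les$suv_mean / les$suv_blood_mean)
  # rc = 1 everywhere and T = 60 gives the same collapse through the
  # enabled path
  les60 <- les
  les60$uptake_time_min <- 60
  on <- correct_cohort(les60, constant_rc_curves(), apply_pvec = TRUE,
                       apply_time = TRUE)
  expect_equal(on$rc_mean, rep(1, nrow(les)), tolerance = 1e-9)
  expect_equal(on$suv_pvec_time_mean, les$suv_mean, tolerance = 1e-9)
  expect_equal(on$sur_pvec_time_peak,
               les60$suv_peak / les60$suv_blood_mean, tolerance = 1e-9)
})

test_that("the pipeline order is partial-volume first, time last", {
  les <- make_lesions(n = 6, seed = 9)
  curves <- test_rc_curves()
  p <- uptake_params()
  out <- correct_cohort(les, curves, p, mode = "approx",
                        peak_voi_ml = NULL)
  # regression-lock the implemented order: pvec -> ratio -> time
  rc <- predict(curves$mean, les$volume_mL)
  sp <- pvec(les$suv_mean, rc, les$suv_bg_local)
  expected <- time_correct_sur(sp / les$suv_blood_mean,
                               les$uptake_time_min, p, "approx")
  expect_equal(out$sur_pvec_time_mean, expected, tolerance = 1e-12)
  # permuting time correction before the partial-volume step changes the
  # answer (the operations do not commute)
  permuted <- pvec(time_correct_suv(les$suv_mean, les$uptake_time_min, p,
                                    "approx"),
                   rc, les$suv_bg_local) / les$suv_blood_mean
  expect_false(isTRUE(all.equal(out$sur_pvec_time_mean, permuted)))
})

test_that("missing inputs are reported by column name", {
  les <- make_lesions()
  les$suv_blood_mean <- NULL
  expect_error(correct_cohort(les, test_rc_curves()), "suv_blood_mean")
  expect_error(correct_cohort(make_lesions()[, 1:4], test_rc_curves()),
               "suv_bg_local")
})

test_that("correct_lesion handles a single record", {
  les <- make_lesions(n = 1)
  out <- correct_lesion(les, test_rc_curves())
  expect_equal(nrow(out), 1L)
  expect_true(all(c("suv_pvec_mean", "sur_pvec_time_max") %in% names(out)))
})
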