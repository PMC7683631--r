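test_that("psf and sphere geometry validate their inputs", {
  expect_error(psf_model(0), "positive")
  expect_error(psf_model(-2), "positive")
  expect_equal(psf_model(6.5)$sigma_mm, 6.5 / (2 * sqrt(2 * log(2))))
  expect_error(sphere_geom(0), "positive")
  expect_error(sphere_geom(10, -1), ">= 0")
})

test_that("ball-Gaussian closed form matches limits and the grid oracle", {
  psf <- psf_model(6.5)
  # interior plateau: blur cannot exceed 1 for a ball much larger than sigma
  expect_equal(ball_gaussian_value(0, 10 * psf$sigma_mm, psf), 1,
               tolerance = 1e-6)
  # far field
  expect_lt(ball_gaussian_value(25, 5, psf), 1e-6)
  # centre of a 5 mm ball at 6.5 mm FWHM: frozen grid-oracle value 0.6497
  expect_equal(ball_gaussian_value(0, 5, psf), 0.650, tolerance = 0.005 / 0.65)
  ora <- grid_ball_gauss(c(0, 3, 5, 8), 5, psf$sigma_mm)
  expect_equal(ball_gaussian_value(c(0, 3, 5, 8), 5, psf), ora,
               tolerance = 0.005)
  expect_error(ball_gaussian_value(-1, 5, psf), ">= 0")
  expect_error(ball_gaussian_value(1, -5, psf), "positive")
})

test_that("walled-sphere profile obeys superposition and the grid oracle", {
  psf <- psf_model(6.5)
  # uniform field is invariant under convolution
  flat <- model_image_profile(sphere_geom(20, 0, 1.5, 1.5), psf)
  expect_equal(flat(c(0, 5, 10, 30)), rep(1.5, 4), tolerance = 1e-12)
  # zero wall reduces to the algebraic two-term form
  g <- sphere_geom(20, 0, 2.26, 1)
  prof <- model_image_profile(g, psf)
  r <- c(0, 4, 9, 10, 12, 20)
  expect_equal(prof(r), 1 + 1.26 * ball_gaussian_value(r, 10, psf),
               tolerance = 1e-12)
  expect_error(sphere_geom(10, -0.5), ">= 0")
})

test_that("profile matches the 3D grid-convolution oracle within 0.5%", {
  psf <- psf_model(6.5)
  for (d in c(10, 13, 17, 22, 28, 37)) {
    g <- sphere_geom(d, 1, 2.26, 1)
    prof <- model_image_profile(g, psf)
    r <- c(0, d / 4, d / 2, d / 2 + 1, d / 2 + 5)
    expect_equal(prof(r), grid_profile(r, g, psf),
                 tolerance = 0.005 / max(grid_profile(r, g, psf)),
                 label = sprintf("profile d=%g", d))
  }
})

test_that("model recovery coefficients behave physically", {
  psf <- psf_model(6.5)
  tiny <- psf_model(0.01)
  g37 <- sphere_geom(37, 0, 2.26, 1)
  # perfect resolution recovers everything
  for (s in c("mean", "peak", "max")) {
    expect_equal(model_rc(g37, tiny, s), 1, tolerance = 1e-4)
  }
  # monotone in diameter, bounded in (0, 1]
  d_seq <- c(10, 13, 17, 22, 28, 37)
  rcs <- vapply(d_seq, function(d) {
    model_rc(sphere_geom(d, 0, 2.26, 1), psf, "mean")
  }, numeric(1))
  expect_true(all(diff(rcs) > 0))
  expect_true(all(rcs > 0 & rcs <= 1))
  expect_gt(rcs[length(rcs)], 0.8)
  # grid-convolution + radial-quadrature oracle at the smallest sphere:
  # VOI mean = 3/R^3 * integral of f(r) r^2 dr with f from the grid oracle
  g10 <- sphere_geom(10, 0, 2.26, 1)
  rr <- seq(0, 5, length.out = 41)
  f <- 1 + 1.26 * grid_ball_gauss(rr, 5, psf$sigma_mm)
  h <- rr[2] - rr[1]
  c_oracle <- 3 / 5^3 * sum((head(f * rr^2, -1) + tail(f * rr^2, -1)) / 2) * h
  rc_oracle <- (c_oracle - 1) / 1.26
  expect_equal(model_rc(g10, psf, "mean"), rc_oracle, tolerance = 0.01)
  # contrast form is invariant under joint activity rescaling
  expect_equal(model_rc(sphere_geom(17, 1, 2.26, 1), psf, "mean"),
               model_rc(sphere_geom(17, 1, 2.26 * 3.7, 3.7), psf, "mean"),
               tolerance = 1e-9)
  expect_error(model_rc(sphere_geom(17, 0, 1, 1), psf, "mean"),
               "denominator")
})

test_that("cold-wall factor magnitudes and limits are as expected", {
  d1 <- sphere_diameter_mm(1)    # 1 mL
  d10 <- sphere_diameter_mm(10.5)
  psf <- psf_model(6.5)
  # exactly 1 at zero wall
  expect_identical(cold_wall_factor(sphere_geom(20, 0, 2.26, 1), psf,
                                    "mean"), 1.0)
  # 1 mL mean-statistic correction in the 8-15% band for FWHM 6-8 mm
  for (f in c(6, 7, 8)) {
    cw <- cold_wall_factor(sphere_geom(d1, 1, 2.26, 1), psf_model(f),
                           "mean")
    expect_gt(cw - 1, 0.08)
    expect_lt(cw - 1, 0.15)
  }
  # max-statistic correction essentially vanishes above 10 mL
  expect_lt(cold_wall_factor(sphere_geom(d10, 1, 2.26, 1), psf, "max") - 1,
            0.01)
  # >= 1 and decreasing toward 1 with volume
  vols <- c(0.5, 1, 2, 5, 10, 25)
  cws <- vapply(vols, function(v) {
    cold_wall_factor(sphere_geom(sphere_diameter_mm(v), 1, 2.26, 1), psf,
                     "mean")
  }, numeric(1))
  expect_true(all(cws >= 1))
  expect_true(all(diff(cws) < 0))
})

test_that("RC curves interpolate knots and extend with model-shaped tails", {
  psf <- psf_model(6.5)
  crv <- build_rc_curve(test_rc_measured(), psf, "mean")
  # knots are hit exactly
  expect_equal(predict(crv, crv$knots$volume_mL), crv$knots$rc,
               tolerance = 1e-10)
  # continuity at the terminal knots
  v_hi <- max(crv$knots$volume_mL)
  v_lo <- min(crv$knots$volume_mL)
  expect_equal(predict(crv, v_hi * (1 + 1e-9)), predict(crv, v_hi),
               tolerance = 1e-6)
  expect_equal(predict(crv, v_lo * (1 - 1e-9)), predict(crv, v_lo),
               tolerance = 1e-6)
  # monotone model tail beyond the largest sphere
  expect_gte(predict(crv, 40), predict(crv, 26.52))
  # mean-statistic curve is monotone non-decreasing over its whole range
  v <- exp(seq(log(0.2), log(43), length.out = 80))
  expect_true(all(diff(predict(crv, v)) >= -1e-9))
  # rejects bad input
  expect_error(build_rc_curve(data.frame(inner_diameter_mm = c(10, 10),
                                         rc = c(0.3, 0.4)), psf, "mean"),
               "duplicate")
  expect_error(predict(crv, -1), "positive")
})

test_that("curve built from noiseless model knots reproduces the model", {
  # end-to-end oracle: feed model-generated wall-free RCs as "measured",
  # no wall correction; the curve must then equal model_rc everywhere
  psf <- psf_model(6.5)
  d_seq <- c(10, 13, 17, 22, 28, 37)
  meas <- data.frame(
    inner_diameter_mm = d_seq,
    rc = vapply(d_seq, function(d) {
      model_rc(sphere_geom(d, 0, 2.26, 1), psf, "mean")
    }, numeric(1))
  )
  crv <- build_rc_curve(meas, psf, "mean", wall_mm = 0)
  v <- c(0.3, 0.52, 1, 2.5, 5, 11.5, 26.52, 35, 60)
  truth <- vapply(v, function(vi) {
    model_rc(sphere_geom(sphere_diameter_mm(vi), 0, 2.26, 1), psf, "mean")
  }, numeric(1))
  expect_equal(predict(crv, v), truth, tolerance = 0.01)
})

test_that("RC tables round-trip through CSV", {
  psf <- psf_model(6.5)
  curves <- test_rc_curves(psf)
  path <- tempfile(fileext = ".csv")
  write_rc_table(curves, path)
  tab <- read_rc_table(path)
  rebuilt <- rc_curves_from_table(tab, psf)
  v <- c(0.5, 2, 10, 30)
  for (s in names(curves)) {
    expect_equal(predict(rebuilt[[s]], v), predict(curves[[s]], v),
                 tolerance = 1e-9)
  }
})
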