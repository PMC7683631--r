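# Independent numerical oracles used across the suite.

# Brute-force value of a unit uniform ball (radius R) convolved with an
# isotropic Gaussian, at distance r from the centre: direct Riemann sum of
# the Gaussian density over a voxelized ball (0.25 mm voxels by default).
# Independent of the closed form in the package.
grid_ball_gauss <- function(r, R, sigma, step = 0.25) {
  ax <- seq(-R + step / 2, R, by = step)
  pts <- expand.grid(x = ax, y = ax, z = ax)
  pts <- pts[pts$x^2 + pts$y^2 + pts$z^2 <= R^2, ]
  norm_c <- (2 * pi * sigma^2)^(-3 / 2) * step^3
  vapply(r, function(ri) {
    d2 <- (pts$x - ri)^2 + pts$y^2 + pts$z^2
    norm_c * sum(exp(-d2 / (2 * sigma^2)))
  }, numeric(1))
}

# Grid-convolution oracle for the walled-sphere radial profile.
grid_profile <- function(r, geom, psf, step = 0.25) {
  r_in <- geom$inner_diameter_mm / 2
  r_out <- r_in + geom$wall_thickness_mm
  inner <- grid_ball_gauss(r, r_in, psf$sigma_mm, step)
  outer <- if (geom$wall_thickness_mm > 0) {
    grid_ball_gauss(r, r_out, psf$sigma_mm, step)
  } else {
    inner
  }
  geom$background_level * (1 - outer) + geom$sphere_level * inner
}

# Rescale a sample to match given moments exactly (for summary-vs-raw
# t-test equivalence checks).
moment_match <- function(x, mean, sd) {
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# Exact two-sided Wilcoxon rank-sum p value by enumeration of all
# group assignments (small n only).
exact_wilcoxon_p <- function(values0, values1) {
  pooled <- c(values0, values1)
  n0 <- length(values0)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n0)])
  combs <- utils::combn(n, n0)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n0 * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Voxel values inside a ball VOI of a phantom image (test-local re-derivation,
# independent of the package's VOI indexing).
voi_values_for_test <- function(image, center, radius) {
  spec <- image$spec
  ax <- lapply(1:3, function(i) {
    n <- spec$grid_dim[i]
    (seq_len(n) - 0.5 - n / 2) * spec$voxel_mm
  })
  keep <- array(FALSE, dim = spec$grid_dim)
  for (i in seq_along(ax[[1]])) {
    for (j in seq_along(ax[[2]])) {
      d2 <- (ax[[1]][i] - center[1])^2 + (ax[[2]][j] - center[2])^2 +
        (ax[[3]] - center[3])^2
      keep[i, j, ] <- d2 <= radius^2
    }
  }
  image$data[keep]
}

# Standard RC curve fixture: measured-like RCs for the six phantom spheres.
test_rc_measured <- function() {
  data.frame(inner_diameter_mm = c(10, 13, 17, 22, 28, 37),
             rc = c(0.30, 0.45, 0.60, 0.72, 0.80, 0.88))
}

test_rc_curves <- function(psf = psf_model(6.5)) {
  meas <- test_rc_measured()
  stats <- c("mean", "peak", "max")
  curves <- lapply(stats, function(s) build_rc_curve(meas, psf, s))
  names(curves) <- stats
  curves
}

# RC curve that evaluates to exactly 1 over the volume range it is built
# on (knots at 0.1 and 100 mL, no wall).
constant_rc_curves <- function(psf = psf_model(6.5)) {
  meas <- data.frame(inner_diameter_mm = sphere_diameter_mm(c(0.1, 100)),
                     rc = c(1, 1))
  stats <- c("mean", "peak", "max")
  curves <- lapply(stats, function(s) {
    build_rc_curve(meas, psf, s, wall_mm = 0)
  })
  names(curves) <- stats
  curves
}

# Exercise run_correct through its file-based interface.
correct_via_files <- function(cfg, cohort, curves) {
  cohort_path <- tempfile(fileext = ".csv")
  rc_path <- tempfile(fileext = ".csv")
  out_path <- tempfile(fileext = ".csv")
  write_cohort_csv(cohort, cohort_path)
  write_rc_table(curves, rc_path)
  cfg$cohort_path <- cohort_path
  cfg$rc_table_path <- rc_path
  cfg$corrected_path <- out_path
  run_correct(cfg)
  read_cohort_csv(out_path)
}

# Independent maximum-likelihood oracle for univariate logistic
# regression: direct Nelder-Mead minimization of the negative
# log-likelihood, no IRLS.
logistic_ml_oracle <- function(x, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * x
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit$par
}
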