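# Analytic recovery-coefficient model: uniform spheres (optionally with a
# cold wall) in warm background, blurred by an isotropic Gaussian PSF.

#' Isotropic Gaussian point-spread-function model
#'
#' The reconstructed-image resolution is modelled as an isotropic Gaussian
#' point-spread function, parameterized by its full width at half maximum.
#'
#' @param fwhm_mm Full width at half maximum in mm; must be positive.
#' @return An object of class `psf_model` with elements `fwhm_mm` and
#'   `sigma_mm` (`fwhm / (2 sqrt(2 log 2))`).
#' @export
#' @examples
#' psf <- psf_model(6.5)
#' psf$sigma_mm
psf_model <- function(fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0) {
    stop("'fwhm_mm' must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(fwhm_mm = fwhm_mm, sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))),
    class = "psf_model"
  )
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("Gaussian PSF: FWHM %.3f mm (sigma %.3f mm)\n",
              x$fwhm_mm, x$sigma_mm))
  invisible(x)
}

#' Hot-sphere geometry with an optional cold wall
#'
#' Describes a uniform hot sphere embedded in uniform warm background. The
#' plastic wall of physical phantom spheres carries no activity
#' ("cold wall"); real lesions have no wall, which is why measured recovery
#' coefficients need a wall correction.
#'
#' @param inner_diameter_mm Inner (active-volume) diameter in mm, positive.
#' @param wall_thickness_mm Cold wall thickness in mm, `>= 0` (default 0).
#' @param sphere_level Relative activity concentration in the sphere
#'   interior (dimensionless, default 2.26).
#' @param background_level Relative background activity concentration
#'   (default 1). The sphere-to-background ratio `SBR` is
#'   `sphere_level / background_level`.
#' @return An object of class `sphere_geom`.
#' @export
sphere_geom <- function(inner_diameter_mm, wall_thickness_mm = 0,
                        sphere_level = 2.26, background_level = 1) {
  if (!is.numeric(inner_diameter_mm) || inner_diameter_mm <= 0) {
    stop("'inner_diameter_mm' must be positive", call. = FALSE)
  }
  if (!is.numeric(wall_thickness_mm) || wall_thickness_mm < 0) {
    stop("'wall_thickness_mm' must be >= 0", call. = FALSE)
  }
  if (background_level < 0 || sphere_level < 0) {
    stop("activity levels must be non-negative", call. = FALSE)
  }
  structure(
    list(inner_diameter_mm = inner_diameter_mm,
         wall_thickness_mm = wall_thickness_mm,
         sphere_level = sphere_level,
         background_level = background_level),
    class = "sphere_geom"
  )
}

#' @export
print.sphere_geom <- function(x, ...) {
  cat(sprintf(
    "Sphere: inner d = %.1f mm (%.2f mL), wall %.1f mm, SBR %.3g\n",
    x$inner_diameter_mm, sphere_volume_ml(x$inner_diameter_mm),
    x$wall_thickness_mm, x$sphere_level / x$background_level))
  invisible(x)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Uniform ball convolved with a Gaussian PSF
#'
#' Value at radial distance `r` of a unit-amplitude uniform ball of radius
#' `R`, convolved with the isotropic Gaussian PSF. Uses the radially
#' symmetric closed form
#' \deqn{f(r) = \tfrac12\left[\mathrm{erf}\frac{R-r}{\sqrt2\sigma} +
#'   \mathrm{erf}\frac{R+r}{\sqrt2\sigma}\right] -
#'   \frac{\sigma}{r\sqrt{2\pi}}\left[e^{-(R-r)^2/2\sigma^2} -
#'   e^{-(R+r)^2/2\sigma^2}\right]}
#' with the analytic limit at the origin substituted for small `r`.
#'
#' @param r Radial distance(s) from the ball centre in mm, `>= 0`.
#' @param R Ball radius in mm, positive.
#' @param psf A [psf_model()].
#' @return Dimensionless intensity in `[0, 1]`, same length as `r`.
#' @export
#' @examples
#' ball_gaussian_value(0, 50, psf_model(6.5)) # ~1: blur bounded by plateau
ball_gaussian_value <- function(r, R, psf) {
  stopifnot(inherits(psf, "psf_model"))
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("'R' must be a single positive radius", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("'r' must be finite and >= 0", call. = FALSE)
  }
  sigma <- psf$sigma_mm
  s2 <- sigma * sqrt(2)
  out <- numeric(length(r))
  # series limit is exact at r = 0 and numerically safer for r << sigma
  near <- r < 1e-8 * max(R, sigma)
  if (any(near)) {
    out[near] <- erf(R / s2) -
      R * sqrt(2 / pi) / sigma * exp(-R^2 / (2 * sigma^2))
  }
  if (any(!near)) {
    rr <- r[!near]
    out[!near] <- 0.5 * (erf((R - rr) / s2) + erf((R + rr) / s2)) -
      sigma / (rr * sqrt(2 * pi)) *
        (exp(-(R - rr)^2 / (2 * sigma^2)) - exp(-(R + rr)^2 / (2 * sigma^2)))
  }
  pmin(pmax(out, 0), 1)
}

#' Radial image profile of a blurred walled sphere in background
#'
#' Superposition profile of background everywhere, minus background over the
#' wall-plus-interior ball, plus the sphere level over the interior ball,
#' each term blurred with the PSF (linearity of convolution). Wall voxels
#' therefore contribute zero activity.
#'
#' @param geom A [sphere_geom()].
#' @param psf A [psf_model()].
#' @return A vectorized function of radial distance `r` (mm) returning the
#'   blurred activity profile.
#' @export
model_image_profile <- function(geom, psf) {
  stopifnot(inherits(geom, "sphere_geom"), inherits(psf, "psf_model"))
  r_in <- geom$inner_diameter_mm / 2
  r_out <- r_in + geom$wall_thickness_mm
  a_b <- geom$background_level
  a_h <- geom$sphere_level
  function(r) {
    a_b * (1 - ball_gaussian_value(r, r_out, psf)) +
      a_h * ball_gaussian_value(r, r_in, psf)
  }
}

# mean of a radial profile over a centred ball of radius R:
# (3 / R^3) * integral_0^R f(r) r^2 dr, split at the given radii to keep
# adaptive quadrature away from near-discontinuities at tiny FWHM
voi_mean_profile <- function(profile, R, split_at = numeric(0)) {
  cuts <- sort(unique(c(0, split_at[split_at > 0 & split_at < R], R)))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    total <- total + stats::integrate(
      function(r) profile(r) * r^2, cuts[i], cuts[i + 1L],
      rel.tol = 1e-9, subdivisions = 400L
    )$value
  }
  3 * total / R^3
}

#' Model recovery coefficient for a sphere statistic
#'
#' Noiseless recovery coefficient of the blurred sphere model for one of the
#' three uptake statistics, in the contrast form
#' \deqn{RC = \frac{C/C_B - 1}{a_H/a_B - 1}}
#' where `C` is the statistic over the sphere-interior VOI (mean), the
#' central profile value (max), or the mean over a centred peak VOI (peak),
#' and `C_B` is the background level (unchanged by blurring far from the
#' sphere).
#'
#' @param geom A [sphere_geom()]; `sphere_level` must differ from
#'   `background_level`.
#' @param psf A [psf_model()].
#' @param statistic One of `"mean"`, `"peak"`, `"max"`.
#' @param peak_voi_ml Volume of the centred peak VOI in mL (default 1.0,
#'   the conventional ~12.4 mm diameter peak sphere).
#' @return Dimensionless recovery coefficient; `<= 1` for the noiseless
#'   model.
#' @export
model_rc <- function(geom, psf, statistic = c("mean", "peak", "max"),
                     peak_voi_ml = 1.0) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(geom, "sphere_geom"), inherits(psf, "psf_model"))
  a_b <- geom$background_level
  a_h <- geom$sphere_level
  if (a_h == a_b) {
    stop("sphere and background levels are equal: contrast denominator is zero",
         call. = FALSE)
  }
  cv <- model_voi_value(geom, psf, statistic, peak_voi_ml)
  (cv / a_b - 1) / (a_h / a_b - 1)
}

# absolute blurred VOI statistic value (activity units) for the sphere model
model_voi_value <- function(geom, psf, statistic, peak_voi_ml = 1.0) {
  r_in <- geom$inner_diameter_mm / 2
  r_out <- r_in + geom$wall_thickness_mm
  profile <- model_image_profile(geom, psf)
  switch(statistic,
    mean = voi_mean_profile(profile, r_in, split_at = c(r_in, r_out)),
    max = profile(0),
    peak = {
      if (!is.numeric(peak_voi_ml) || peak_voi_ml <= 0) {
        stop("'peak_voi_ml' must be positive", call. = FALSE)
      }
      r_peak <- sphere_diameter_mm(peak_voi_ml) / 2
      voi_mean_profile(profile, r_peak, split_at = c(r_in, r_out))
    }
  )
}

#' Cold-wall correction factor
#'
#' Ratio of the simulated uptake statistic for a sphere without and with its
#' cold wall, at the same inner diameter: the wall of physical phantom
#' spheres is inactive plastic, absent in real lesions, so measured
#' recovery coefficients are multiplied by this factor before use on
#' lesions. The ratio is taken on the absolute blurred VOI statistic values
#' (not on the background-subtracted contrast form): at a 2.26
#' sphere-to-background ratio and 6-8 mm FWHM this yields a ~10% correction
#' for a 1 mL sphere (mean statistic), falling under 5% above 10 mL and
#' essentially vanishing for the max statistic of large spheres, the
#' magnitudes expected of this correction. The factor is `>= 1` for a hot
#' sphere with a cold wall and decreases toward 1 as the volume grows.
#'
#' @inheritParams model_rc
#' @return Dimensionless factor `>= 1` (exactly 1 at zero wall thickness).
#' @export
cold_wall_factor <- function(geom, psf, statistic = c("mean", "peak", "max"),
                             peak_voi_ml = 1.0) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(geom, "sphere_geom"))
  if (geom$wall_thickness_mm == 0) return(1.0)
  no_wall <- sphere_geom(geom$inner_diameter_mm, 0,
                         geom$sphere_level, geom$background_level)
  model_voi_value(no_wall, psf, statistic, peak_voi_ml) /
    model_voi_value(geom, psf, statistic, peak_voi_ml)
}

#' Build a recovery-coefficient curve from per-sphere measurements
#'
#' Turns a table of measured per-sphere recovery coefficients into a
#' continuous RC-versus-volume curve: each measured RC is multiplied by its
#' cold-wall correction factor to form a knot at the sphere's inner volume;
#' between knots the curve is a monotone piecewise-cubic interpolant in
#' (log10 volume, RC); beyond the largest knot and below the smallest the
#' curve follows the analytic model RC shape rescaled to pass through the
#' terminal knot, so evaluation is continuous over all positive volumes.
#'
#' @param measured Data frame with columns `inner_diameter_mm` and `rc`
#'   (measured recovery coefficients), at least two rows with distinct
#'   diameters.
#' @param psf A [psf_model()] used for the wall correction and the model
#'   tails.
#' @param statistic One of `"mean"`, `"peak"`, `"max"`.
#' @param wall_mm Cold-wall thickness of the measured spheres in mm
#'   (default 1).
#' @param model_sbr Sphere-to-background ratio used in the model (default
#'   2.26, between the phantom fill ratio and the patient tumor-to-liver
#'   ratio).
#' @param peak_voi_ml Peak VOI volume in mL.
#' @return An object of class `rc_curve`; evaluate with
#'   [predict.rc_curve()]. Carries the knot table (columns `statistic`,
#'   `inner_diameter_mm`, `volume_mL`, `rc_measured`, `wall_factor`,
#'   `rc_final`) as component `$table`.
#' @export
build_rc_curve <- function(measured, psf, statistic = c("mean", "peak", "max"),
                           wall_mm = 1, model_sbr = 2.26, peak_voi_ml = 1.0) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(measured),
            all(c("inner_diameter_mm", "rc") %in% names(measured)))
  if (nrow(measured) < 2L) {
    stop("need at least two measured spheres", call. = FALSE)
  }
  d <- measured$inner_diameter_mm
  if (anyDuplicated(d)) stop("duplicate sphere diameters", call. = FALSE)
  o <- order(d)
  d <- d[o]
  rc_meas <- measured$rc[o]
  if (any(rc_meas <= 0)) stop("measured rc must be positive", call. = FALSE)

  wall_factor <- vapply(d, function(di) {
    cold_wall_factor(sphere_geom(di, wall_mm, model_sbr, 1), psf,
                     statistic, peak_voi_ml)
  }, numeric(1))
  vol <- sphere_volume_ml(d)
  rc_final <- rc_meas * wall_factor

  interp <- stats::splinefun(log10(vol), rc_final, method = "monoH.FC")
  model_at <- function(v) {
    vapply(v, function(vi) {
      model_rc(sphere_geom(sphere_diameter_mm(vi), 0, model_sbr, 1),
               psf, statistic, peak_voi_ml)
    }, numeric(1))
  }
  k <- length(vol)
  scale_lo <- rc_final[1L] / model_at(vol[1L])
  scale_hi <- rc_final[k] / model_at(vol[k])

  structure(
    list(statistic = statistic,
         knots = data.frame(volume_mL = vol, rc = rc_final),
         table = data.frame(statistic = statistic,
                            inner_diameter_mm = d,
                            volume_mL = vol,
                            rc_measured = rc_meas,
                            wall_factor = wall_factor,
                            rc_final = rc_final),
         interp = interp,
         model_at = model_at,
         scale_lo = scale_lo,
         scale_hi = scale_hi,
         psf = psf,
         model_sbr = model_sbr,
         peak_voi_ml = peak_voi_ml),
    class = "rc_curve"
  )
}

#' Evaluate a recovery-coefficient curve
#'
#' @param object An `rc_curve` from [build_rc_curve()].
#' @param volume_ml Lesion volume(s) in mL, positive.
#' @param ... Unused.
#' @return Recovery coefficient(s) at the requested volume(s).
#' @export
predict.rc_curve <- function(object, volume_ml, ...) {
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0)) {
    stop("'volume_ml' must be positive and finite", call. = FALSE)
  }
  v <- object$knots$volume_mL
  lo <- v[1L]
  hi <- v[length(v)]
  out <- numeric(length(volume_ml))
  mid <- volume_ml >= lo & volume_ml <= hi
  if (any(mid)) out[mid] <- object$interp(log10(volume_ml[mid]))
  below <- volume_ml < lo
  if (any(below)) {
    out[below] <- object$scale_lo * object$model_at(volume_ml[below])
  }
  above <- volume_ml > hi
  if (any(above)) {
    out[above] <- object$scale_hi * object$model_at(volume_ml[above])
  }
  out
}

#' @export
print.rc_curve <- function(x, ...) {
  cat(sprintf("RC curve (%s statistic), %d knots over %.2f-%.2f mL\n",
              x$statistic, nrow(x$knots), min(x$knots$volume_mL),
              max(x$knots$volume_mL)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write / read recovery-coefficient tables
#'
#' The knot tables of one or more `rc_curve` objects are persisted as a
#' plain CSV with columns `statistic`, `inner_diameter_mm`, `volume_mL`,
#' `rc_measured`, `wall_factor`, `rc_final`.
#'
#' @param curves A single `rc_curve` or a list of them.
#' @param path CSV file path.
#' @return `write_rc_table` returns `path` invisibly; `read_rc_table`
#'   returns the table as a data frame.
#' @export
write_rc_table <- function(curves, path) {
  if (inherits(curves, "rc_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, `[[`, "table"))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rc_table
#' @export
read_rc_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rebuild RC curves from a persisted table
#'
#' @param table Data frame as returned by [read_rc_table()].
#' @param psf A [psf_model()].
#' @inheritParams build_rc_curve
#' @return Named list of `rc_curve` objects, one per statistic present.
#' @export
rc_curves_from_table <- function(table, psf, wall_mm = 1, model_sbr = 2.26,
                                 peak_voi_ml = 1.0) {
  stopifnot(all(c("statistic", "inner_diameter_mm", "rc_measured") %in%
                  names(table)))
  stats_present <- unique(table$statistic)
  curves <- lapply(stats_present, function(s) {
    sub <- table[table$statistic == s, ]
    build_rc_curve(
      data.frame(inner_diameter_mm = sub$inner_diameter_mm,
                 rc = sub$rc_measured),
      psf, s, wall_mm = wall_mm, model_sbr = model_sbr,
      peak_voi_ml = peak_voi_ml
    )
  })
  names(curves) <- stats_present
  curves
}
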