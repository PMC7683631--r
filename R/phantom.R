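# Digital image-quality phantom: voxelized spheres with cold walls in warm
# background, Gaussian-blurred, optionally noisy; measured-RC extraction.

#' NEMA-like sphere set
#'
#' The six image-quality phantom spheres (inner diameters 10, 13, 17, 22,
#' 28 and 37 mm, 1 mm cold walls) arranged coplanar on a ring, as in the
#' physical phantom.
#'
#' @param ring_radius_mm Radius of the sphere ring in mm (default 57.2, the
#'   standard sphere-centre ring).
#' @param wall_mm Wall thickness in mm.
#' @return Data frame with columns `inner_diameter_mm`, `wall_mm`, `x_mm`,
#'   `y_mm`, `z_mm` (centre coordinates relative to the grid centre).
#' @export
nema_spheres <- function(ring_radius_mm = 57.2, wall_mm = 1) {
  d <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(d) - 1) * pi / 3
  data.frame(
    inner_diameter_mm = d,
    wall_mm = wall_mm,
    x_mm = ring_radius_mm * cos(ang),
    y_mm = ring_radius_mm * sin(ang),
    z_mm = 0
  )
}

#' Digital phantom specification
#'
#' Describes a voxel grid holding hot spheres (with cold walls) in warm
#' background with a central zero-activity lung-insert cylinder, the PSF to
#' blur with, and an optional per-voxel Gaussian noise level. Default
#' activities reproduce the 2.19:1 sphere-to-background fill
#' (9.284 / 4.240 kBq/mL).
#'
#' @param grid_dim Integer vector of three voxel counts (default
#'   `c(200, 200, 120)`).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param spheres Data frame as from [nema_spheres()]; centres are relative
#'   to the grid centre. May have zero rows.
#' @param background_kbq_ml Background activity concentration (default
#'   4.240).
#' @param sphere_kbq_ml Sphere interior activity concentration (default
#'   9.284).
#' @param lung_insert `NULL` for none, or a list with `radius_mm` (default
#'   a 25 mm-radius zero-activity cylinder through the grid centre along z).
#' @param psf A [psf_model()].
#' @param noise_sd Relative Gaussian noise per voxel, as a fraction of the
#'   background level (default 0).
#' @param seed Integer seed for the noise draw (default 1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(200, 200, 120), voxel_mm = 2,
                         spheres = nema_spheres(),
                         background_kbq_ml = 4.240, sphere_kbq_ml = 9.284,
                         lung_insert = list(radius_mm = 25),
                         psf = psf_model(6.5), noise_sd = 0, seed = 1L) {
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim > 0), voxel_mm > 0,
            background_kbq_ml >= 0, sphere_kbq_ml >= 0, noise_sd >= 0,
            inherits(psf, "psf_model"))
  if (!is.null(spheres) && nrow(spheres)) {
    need <- c("inner_diameter_mm", "wall_mm", "x_mm", "y_mm", "z_mm")
    stopifnot(all(need %in% names(spheres)))
    half <- grid_dim * voxel_mm / 2
    r_out <- spheres$inner_diameter_mm / 2 + spheres$wall_mm
    inside <- abs(spheres$x_mm) + r_out <= half[1] &
      abs(spheres$y_mm) + r_out <= half[2] &
      abs(spheres$z_mm) + r_out <= half[3]
    if (!all(inside)) {
      stop("sphere(s) ", paste(which(!inside), collapse = ", "),
           " do not lie fully inside the grid", call. = FALSE)
    }
  }
  structure(
    list(grid_dim = grid_dim, voxel_mm = voxel_mm, spheres = spheres,
         background_kbq_ml = background_kbq_ml,
         sphere_kbq_ml = sphere_kbq_ml, lung_insert = lung_insert,
         psf = psf, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# voxel-centre coordinate axes (mm, origin at grid centre)
phantom_axes <- function(spec) {
  lapply(1:3, function(i) {
    n <- spec$grid_dim[i]
    (seq_len(n) - 0.5 - n / 2) * spec$voxel_mm
  })
}

# partial-volume-accurate indicator of a ball on the grid: voxels fully
# inside/outside are set analytically, boundary voxels by nsub^3 subsampling
ball_fraction_grid <- function(spec, center, radius, nsub = 3L) {
  ax <- phantom_axes(spec)
  dims <- spec$grid_dim
  vox <- spec$voxel_mm
  frac <- array(0, dim = dims)
  half_diag <- vox * sqrt(3) / 2
  ix <- which(abs(ax[[1]] - center[1]) <= radius + half_diag)
  iy <- which(abs(ax[[2]] - center[2]) <= radius + half_diag)
  iz <- which(abs(ax[[3]] - center[3]) <= radius + half_diag)
  if (!length(ix) || !length(iy) || !length(iz)) return(frac)
  dx2 <- (ax[[1]][ix] - center[1])^2
  dy2 <- (ax[[2]][iy] - center[2])^2
  dz2 <- (ax[[3]][iz] - center[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  sub <- array(0, dim = dim(dist))
  sub[dist <= radius - half_diag] <- 1
  border <- which(dist > radius - half_diag & dist < radius + half_diag,
                  arr.ind = TRUE)
  if (nrow(border)) {
    off <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * vox
    grid3 <- expand.grid(ox = off, oy = off, oz = off)
    for (k in seq_len(nrow(border))) {
      cx <- ax[[1]][ix[border[k, 1]]] - center[1]
      cy <- ax[[2]][iy[border[k, 2]]] - center[2]
      cz <- ax[[3]][iz[border[k, 3]]] - center[3]
      d2 <- (cx + grid3$ox)^2 + (cy + grid3$oy)^2 + (cz + grid3$oz)^2
      sub[border[k, 1], border[k, 2], border[k, 3]] <- mean(d2 <= radius^2)
    }
  }
  frac[ix, iy, iz] <- sub
  frac
}

# infinite cylinder along z, subsampled in-plane
cylinder_fraction_grid <- function(spec, radius, nsub = 3L) {
  ax <- phantom_axes(spec)
  vox <- spec$voxel_mm
  half_diag <- vox * sqrt(2) / 2
  dx <- ax[[1]]
  dy <- ax[[2]]
  dist <- sqrt(outer(dx^2, dy^2, "+"))
  plane <- matrix(0, nrow = length(dx), ncol = length(dy))
  plane[dist <= radius - half_diag] <- 1
  border <- which(dist > radius - half_diag & dist < radius + half_diag,
                  arr.ind = TRUE)
  if (nrow(border)) {
    off <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * vox
    grid2 <- expand.grid(ox = off, oy = off)
    for (k in seq_len(nrow(border))) {
      cx <- dx[border[k, 1]]
      cy <- dy[border[k, 2]]
      d2 <- (cx + grid2$ox)^2 + (cy + grid2$oy)^2
      plane[border[k, 1], border[k, 2]] <- mean(d2 <= radius^2)
    }
  }
  array(rep(plane, spec$grid_dim[3]), dim = spec$grid_dim)
}

# periodic FFT convolution with an isotropic Gaussian kernel
gaussian_blur3d <- function(img, sigma_mm, voxel_mm) {
  if (sigma_mm <= 0) return(img)
  dims <- dim(img)
  kern1d <- lapply(dims, function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * voxel_mm
    k <- exp(-x^2 / (2 * sigma_mm^2))
    k / sum(k)
  })
  kern <- outer(outer(kern1d[[1]], kern1d[[2]]), kern1d[[3]])
  dim(kern) <- dims
  out <- Re(stats::fft(stats::fft(img) * stats::fft(kern), inverse = TRUE)) /
    prod(dims)
  out
}

#' Render a digital phantom image
#'
#' Voxelizes the phantom activity distribution (background everywhere, zero
#' in the cold walls and the lung insert, sphere level in the sphere
#' interiors; partial-volume-accurate voxelization by 3^3 subsampling at
#' object boundaries), blurs it with the Gaussian PSF, and optionally adds
#' zero-mean Gaussian noise with standard deviation
#' `noise_sd * background_kbq_ml`. Deterministic for a given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param nsub Boundary-subsampling factor per axis (default 3).
#' @return An object of class `phantom_image`: list with the 3D `data`
#'   array (kBq/mL) and the `spec`.
#' @export
render_phantom <- function(spec, nsub = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- array(spec$background_kbq_ml, dim = spec$grid_dim)
  if (!is.null(spec$spheres) && nrow(spec$spheres)) {
    for (i in seq_len(nrow(spec$spheres))) {
      s <- spec$spheres[i, ]
      ctr <- c(s$x_mm, s$y_mm, s$z_mm)
      r_in <- s$inner_diameter_mm / 2
      f_in <- ball_fraction_grid(spec, ctr, r_in, nsub)
      if (s$wall_mm > 0) {
        f_out <- ball_fraction_grid(spec, ctr, r_in + s$wall_mm, nsub)
      } else {
        f_out <- f_in
      }
      img <- img - spec$background_kbq_ml * f_out + spec$sphere_kbq_ml * f_in
    }
  }
  if (!is.null(spec$lung_insert)) {
    f_cyl <- cylinder_fraction_grid(spec, spec$lung_insert$radius_mm, nsub)
    img <- img - spec$background_kbq_ml * f_cyl
  }
  img <- gaussian_blur3d(img, spec$psf$sigma_mm, spec$voxel_mm)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + array(
      stats::rnorm(prod(spec$grid_dim), 0,
                   spec$noise_sd * spec$background_kbq_ml),
      dim = spec$grid_dim
    )
  }
  structure(list(data = img, spec = spec), class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("Phantom image %s at %.2f mm (range %.3f-%.3f kBq/mL)\n",
              paste(dim(x$data), collapse = "x"), x$spec$voxel_mm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Default background ROI layout
#'
#' Twelve spherical background ROIs on the sphere ring radius, rotated 30
#' degrees off the sphere positions and offset +-`z_offset_mm` axially, so
#' they sample the warm compartment away from the spheres and the lung
#' insert. A documented stand-in for the standard's full background-ROI
#' layout, sufficient for synthetic phantoms.
#'
#' @param spec A [phantom_spec()].
#' @param ring_radius_mm Ring radius for the ROI centres (default 57.2).
#' @param z_offset_mm Axial offset of the two ROI planes (default 30).
#' @return Matrix with one row per ROI centre (x, y, z in mm).
#' @export
background_roi_centers <- function(spec, ring_radius_mm = 57.2,
                                   z_offset_mm = 30) {
  ang <- (0:5) * pi / 3 + pi / 6
  ctr <- cbind(ring_radius_mm * cos(ang), ring_radius_mm * sin(ang))
  rbind(cbind(ctr, z_offset_mm), cbind(ctr, -z_offset_mm))
}

# mean of image over a ball VOI (voxel-centre membership)
voi_indices <- function(spec, center, radius) {
  ax <- phantom_axes(spec)
  ix <- which(abs(ax[[1]] - center[1]) <= radius)
  iy <- which(abs(ax[[2]] - center[2]) <= radius)
  iz <- which(abs(ax[[3]] - center[3]) <= radius)
  if (!length(ix) || !length(iy) || !length(iz)) {
    stop("VOI lies outside the image grid", call. = FALSE)
  }
  dist <- sqrt(outer(outer((ax[[1]][ix] - center[1])^2,
                           (ax[[2]][iy] - center[2])^2, "+"),
                     (ax[[3]][iz] - center[3])^2, "+"))
  keep <- which(dist <= radius, arr.ind = TRUE)
  cbind(ix[keep[, 1]], iy[keep[, 2]], iz[keep[, 3]])
}

voi_values <- function(image, center, radius) {
  idx <- voi_indices(image$spec, center, radius)
  image$data[idx]
}

#' Measure per-sphere recovery coefficients on a phantom image
#'
#' For each sphere, a spherical VOI matching the inner diameter is centred
#' at the known sphere centre; the requested statistic `C` (mean over the
#' VOI, maximum voxel, or mean over a peak VOI centred at the hottest voxel)
#' and the mean background `C_B` over the background ROIs give the
#' contrast-form recovery coefficient
#' `((C / C_B) - 1) / ((a_H / a_B) - 1)`.
#'
#' @param image A `phantom_image` from [render_phantom()].
#' @param statistic One of `"mean"`, `"peak"`, `"max"`.
#' @param peak_voi_ml Peak VOI volume in mL (default 1.0).
#' @param bg_centers Matrix of background ROI centres (mm); default
#'   [background_roi_centers()] of the image's spec.
#' @param bg_roi_diameter_mm Background ROI diameter (default 37).
#' @param min_voi_voxels Minimum voxels per sphere VOI (default 8); smaller
#'   VOIs are rejected as unresolvable.
#' @return Data frame with columns `inner_diameter_mm`, `volume_mL`,
#'   `statistic`, `c_hot`, `c_bg`, `rc`.
#' @export
measure_rc <- function(image, statistic = c("mean", "peak", "max"),
                       peak_voi_ml = 1.0, bg_centers = NULL,
                       bg_roi_diameter_mm = 37, min_voi_voxels = 8L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(image, "phantom_image"))
  spec <- image$spec
  if (is.null(spec$spheres) || !nrow(spec$spheres)) {
    stop("phantom spec contains no spheres to measure", call. = FALSE)
  }
  a_h <- spec$sphere_kbq_ml
  a_b <- spec$background_kbq_ml
  if (a_h == a_b) {
    stop("sphere and background activities are equal: contrast denominator is zero",
         call. = FALSE)
  }
  if (is.null(bg_centers)) bg_centers <- background_roi_centers(spec)
  bg_vals <- unlist(lapply(seq_len(nrow(bg_centers)), function(i) {
    voi_values(image, bg_centers[i, ], bg_roi_diameter_mm / 2)
  }))
  c_bg <- mean(bg_vals)

  ax <- phantom_axes(spec)
  res <- lapply(seq_len(nrow(spec$spheres)), function(i) {
    s <- spec$spheres[i, ]
    ctr <- c(s$x_mm, s$y_mm, s$z_mm)
    r_in <- s$inner_diameter_mm / 2
    idx <- voi_indices(spec, ctr, r_in)
    if (nrow(idx) < min_voi_voxels && statistic == "mean") {
      stop(sprintf("sphere %d VOI has only %d voxels (need >= %d)",
                   i, nrow(idx), min_voi_voxels), call. = FALSE)
    }
    vals <- image$data[idx]
    c_hot <- switch(statistic,
      mean = mean(vals),
      max = max(vals),
      peak = {
        k <- idx[which.max(vals), ]
        peak_ctr <- c(ax[[1]][k[1]], ax[[2]][k[2]], ax[[3]][k[3]])
        mean(voi_values(image, peak_ctr,
                        sphere_diameter_mm(peak_voi_ml) / 2))
      }
    )
    data.frame(inner_diameter_mm = s$inner_diameter_mm,
               volume_mL = sphere_volume_ml(s$inner_diameter_mm),
               statistic = statistic, c_hot = c_hot, c_bg = c_bg,
               rc = (c_hot / c_bg - 1) / (a_h / a_b - 1))
  })
  do.call(rbind, res)
}

#' Persist / load a phantom image as raw binary plus JSON sidecar
#'
#' The voxel data are written as little-endian 8-byte doubles in column
#' order with a JSON sidecar (`<path>.json`) recording grid shape, voxel
#' size, activities, PSF, noise level and seed, so a volume can be
#' round-tripped without any imaging-format dependency.
#'
#' @param image A `phantom_image`.
#' @param path Path for the binary voxel file; the sidecar is `<path>.json`.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` returns
#'   a `phantom_image`.
#' @export
write_phantom <- function(image, path) {
  stopifnot(inherits(image, "phantom_image"))
  spec <- image$spec
  meta <- list(
    grid_dim = spec$grid_dim, voxel_mm = spec$voxel_mm,
    background_kbq_ml = spec$background_kbq_ml,
    sphere_kbq_ml = spec$sphere_kbq_ml,
    psf_fwhm_mm = spec$psf$fwhm_mm, noise_sd = spec$noise_sd,
    seed = spec$seed,
    lung_insert_radius_mm = if (is.null(spec$lung_insert)) NULL else
      spec$lung_insert$radius_mm,
    spheres = spec$spheres,
    dtype = "float64-little", order = "column-major"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(image$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spheres <- if (!is.null(meta$spheres) && length(meta$spheres)) {
    as.data.frame(meta$spheres)
  } else NULL
  spec <- phantom_spec(
    grid_dim = meta$grid_dim, voxel_mm = meta$voxel_mm, spheres = spheres,
    background_kbq_ml = meta$background_kbq_ml,
    sphere_kbq_ml = meta$sphere_kbq_ml,
    lung_insert = if (is.null(meta$lung_insert_radius_mm)) NULL else
      list(radius_mm = meta$lung_insert_radius_mm),
    psf = psf_model(meta$psf_fwhm_mm), noise_sd = meta$noise_sd,
    seed = meta$seed
  )
  con <- file(path, "rb")
  on.exit(close(con))
  n <- prod(spec$grid_dim)
  dat <- readBin(con, "double", n = n, size = 8, endian = "little")
  structure(list(data = array(dat, dim = spec$grid_dim), spec = spec),
            class = "phantom_image")
}
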