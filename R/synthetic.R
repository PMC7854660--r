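#' Phantom specification for the synthetic burst-mode speckle simulator
#'
#' Describes a coherent-speckle phantom emulating the structure of a
#' burst-mode OCM time-lapse of a spheroid in a collagen gel: a static,
#' fully developed collagen speckle field; a spheroid-shaped region (with
#' cylindrical protrusions) whose speckle decorrelates from burst frame to
#' burst frame; a smooth radial contraction of the collagen; per-time-point
#' lateral stage drift; a depth-dependent additive background; and additive
#' Gaussian amplitude noise.
#'
#' Scatterers are modelled as a circular complex Gaussian field (variance
#' proportional to `density`) convolved with a Gaussian point-spread
#' function, so the amplitude is Rayleigh-distributed (fully developed
#' speckle). Cell speckle is a complex AR(1) process across burst frames
#' with coefficient `sqrt(rho)`, which makes the consecutive-frame
#' *amplitude* correlation approximately `rho`.
#'
#' @param grid a [voxel_grid()]; default 128 x 128 x 96 voxels at 1.88 um.
#' @param center_um spheroid center (um); defaults to the grid center.
#' @param radius_um spheroid radius R (um).
#' @param n_protrusions,protrusion_length_um,protrusion_width_um cylindrical
#'   protrusions radiating from the spheroid surface.
#' @param growth_um_per_step increase of radius and protrusion length per
#'   time step (um); 0 freezes the mask.
#' @param density scatterer density (complex field variance) per voxel.
#' @param psf_sigma_um Gaussian PSF widths (lateral, axial) in um.
#' @param rho consecutive-frame amplitude correlation of cell speckle,
#'   in \[0, 1\].
#' @param cell_gain mean cell amplitude relative to mean collagen amplitude.
#' @param contraction_A_um far-field contraction amplitude at r = R (um),
#'   reached at the last time-point via a linear ramp.
#' @param contraction_p far-field decay exponent.
#' @param drift_um_per_step lateral drift per time step, (dx, dy) in um.
#' @param background_peak additive background amplitude at z = 0 (the
#'   profile decays as `exp(-3 z / nz)`), on the scale of unit mean
#'   collagen amplitude.
#' @param noise_sd additive Gaussian amplitude noise s.d.
#' @param interval_min time between time-points, minutes.
#' @param seed integer seed; every random draw derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = voxel_grid(c(128L, 128L, 96L), pitch = 1.88),
                         center_um = NULL,
                         radius_um = 55,
                         n_protrusions = 4L,
                         protrusion_length_um = 35,
                         protrusion_width_um = 8,
                         growth_um_per_step = 0,
                         density = 2,
                         psf_sigma_um = c(1.5, 2.4),
                         rho = 0.2,
                         cell_gain = 1.5,
                         contraction_A_um = 4,
                         contraction_p = 2,
                         drift_um_per_step = c(0, 0),
                         background_peak = 0.25,
                         noise_sd = 0.05,
                         interval_min = 40,
                         seed = 1L) {
  if (is.null(center_um)) center_um <- grid$origin + (grid$shape - 1) * grid$pitch / 2
  if (rho < 0 || rho > 1) stop("`rho` must be in [0, 1]")
  if (radius_um <= 0) stop("`radius_um` must be > 0")
  if (contraction_A_um < 0) stop("`contraction_A_um` must be >= 0")
  if (contraction_p <= 0) stop("`contraction_p` must be > 0")
  if (density < 0) stop("`density` must be >= 0")
  psf <- as.numeric(psf_sigma_um)
  if (length(psf) == 2L) psf <- c(psf[1], psf[1], psf[2])
  if (any(psf <= 0)) stop("PSF widths must be > 0")
  ext <- grid_extent(grid)
  lo <- center_um - grid$origin
  hi <- grid$origin + ext - center_um
  margin <- radius_um + max(psf)
  if (any(lo < margin) || any(hi < margin))
    stop("spheroid does not fit inside the grid with a PSF-width margin")
  nz <- grid$shape[3]
  background <- background_peak * exp(-3 * (0:(nz - 1)) / nz)
  structure(list(grid = grid, center_um = center_um, radius_um = radius_um,
                 n_protrusions = as.integer(n_protrusions),
                 protrusion_length_um = protrusion_length_um,
                 protrusion_width_um = protrusion_width_um,
                 growth_um_per_step = growth_um_per_step,
                 density = density, psf_sigma_um = psf, rho = rho,
                 cell_gain = cell_gain,
                 contraction_A_um = contraction_A_um,
                 contraction_p = contraction_p,
                 drift_um_per_step = as.numeric(drift_um_per_step),
                 background = background, noise_sd = noise_sd,
                 interval_min = interval_min, seed = as.integer(seed)),
            class = "phantom_spec")
}

# complex circular Gaussian scatterer field blurred by the PSF; returns a
# list(re, im) of 3D arrays with (approximately) unit total variance per voxel
speckle_complex_field <- function(shape, psf_sigma_vox, density) {
  n <- prod(shape)
  re <- array(stats::rnorm(n), shape)
  im <- array(stats::rnorm(n), shape)
  re <- gauss_blur(re, psf_sigma_vox, wrap = TRUE)
  im <- gauss_blur(im, psf_sigma_vox, wrap = TRUE)
  # renormalise: blurring shrinks the variance by the kernel energy
  s <- sqrt(mean(re^2 + im^2) / 2)
  scale <- sqrt(density) / s
  list(re = re * scale, im = im * scale)
}

#' Static collagen speckle volume
#'
#' Fully developed speckle from quasi-static scatterers: a seeded complex
#' Gaussian scatterer field is convolved with the Gaussian PSF and the
#' magnitude taken, then normalised to unit mean amplitude. The amplitude is
#' Rayleigh-distributed, with contrast (s.d./mean) `sqrt(4/pi - 1) ~ 0.52`.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume_image()] of linear amplitude.
#' @export
make_collagen_speckle <- function(spec) {
  g <- spec$grid
  psf_vox <- spec$psf_sigma_um / g$pitch
  if (any(2 * ceiling(3 * psf_vox) + 1 > g$shape))
    stop("PSF is wider than the grid")
  if (spec$density == 0)
    return(volume_image(array(0, g$shape), g, role = "raw"))
  set.seed(spec$seed)
  f <- speckle_complex_field(g$shape, psf_vox, spec$density)
  amp <- sqrt(f$re^2 + f$im^2)
  amp <- amp / mean(amp)
  volume_image(amp, g, role = "raw")
}

#' Spheroid-plus-protrusions binary mask
#'
#' A sphere of radius R centered at the phantom center plus
#' `n_protrusions` cylindrical protrusions radiating outward in fixed
#' (seed-derived) directions. With `growth_um_per_step > 0` the radius and
#' protrusion length grow linearly with the time step, so masks are nested
#' over time.
#'
#' @param spec a [phantom_spec()].
#' @param step time step index (0-based) used for growth.
#' @return A binary [volume_image()] (`role = "binary_mask"`).
#' @export
make_spheroid_mask <- function(spec, step = 0) {
  g <- spec$grid
  R <- spec$radius_um + spec$growth_um_per_step * step
  L <- spec$protrusion_length_um + spec$growth_um_per_step * step
  if (R <= 0) return(volume_image(array(0, g$shape), g, role = "binary_mask"))
  cx <- (spec$center_um - g$origin) / g$pitch   # center in voxel coords
  xs <- (0:(g$shape[1] - 1)) - cx[1]
  ys <- (0:(g$shape[2] - 1)) - cx[2]
  zs <- (0:(g$shape[3] - 1)) - cx[3]
  # physical offsets (um) per axis
  X <- xs * g$pitch[1]; Y <- ys * g$pitch[2]; Z <- zs * g$pitch[3]
  r2 <- outer(outer(X^2, Y^2, `+`), Z^2, `+`)
  mask <- r2 <= R^2
  if (spec$n_protrusions > 0L && L > 0) {
    set.seed(spec$seed + 7L)
    # fixed quasi-uniform directions on the sphere
    dirs <- matrix(stats::rnorm(3L * spec$n_protrusions), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    w2 <- (spec$protrusion_width_um / 2)^2
    coords <- list(X, Y, Z)
    for (k in seq_len(spec$n_protrusions)) {
      d <- dirs[k, ]
      # distance along the axis and squared distance to it, per voxel
      proj <- outer(outer(X * d[1], Y * d[2], `+`), Z * d[3], `+`)
      perp2 <- r2 - proj^2
      mask <- mask | (proj >= 0 & proj <= R + L & perp2 <= w2)
    }
  }
  volume_image(array(as.numeric(mask), g$shape), g, role = "binary_mask")
}

#' Simulate one burst of N frames with decorrelating cell speckle
#'
#' Outside the mask all N frames equal the static volume (temporally frozen
#' collagen speckle). Inside the mask each frame is the magnitude of a
#' complex AR(1) speckle process with coefficient `sqrt(rho)`, so the
#' consecutive-frame amplitude correlation is approximately `rho`
#' (`rho = 1` freezes the cell speckle, `rho = 0` fully decorrelates it).
#' No background or noise is added here; [generate_timelapse()] adds those.
#'
#' @param static a [volume_image()], the frozen collagen amplitude.
#' @param mask a binary [volume_image()] marking the cell region.
#' @param rho consecutive-frame amplitude correlation in \[0, 1\].
#' @param N number of frames (>= 2).
#' @param seed integer seed.
#' @param psf_sigma_um PSF widths (um) for the cell speckle grain.
#' @param cell_gain mean cell amplitude relative to the static volume scale.
#' @return A [burst_stack()] of N frames.
#' @export
simulate_burst <- function(static, mask, rho, N, seed,
                           psf_sigma_um = c(1.5, 1.5, 2.4), cell_gain = 1.5) {
  if (N < 2L) stop("`N` must be >= 2")
  g <- static$grid
  if (!identical(g$shape, mask$grid$shape)) stop("static/mask shape mismatch")
  inside <- mask$data == 1
  if (!any(inside)) {
    return(burst_stack(rep(list(static$data), N), g, timestamp = static$timestamp))
  }
  psf <- as.numeric(psf_sigma_um)
  if (length(psf) == 2L) psf <- c(psf[1], psf[1], psf[2])
  psf_vox <- psf / g$pitch
  # bounding box of the mask padded by the PSF support
  idx <- which(inside, arr.ind = TRUE)
  pad <- ceiling(3 * psf_vox)
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, g$shape)
  bshape <- hi - lo + 1L
  set.seed(seed)
  phi <- sqrt(rho)
  z <- speckle_complex_field(bshape, psf_vox, 1)
  sub_inside <- inside[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  # mean amplitude of a unit-variance-per-component Rayleigh is sqrt(pi/2)
  amp_scale <- cell_gain * mean(static$data[!inside]) / sqrt(pi / 2)
  if (!is.finite(amp_scale) || amp_scale <= 0) amp_scale <- cell_gain
  frames <- vector("list", N)
  for (i in seq_len(N)) {
    if (i > 1L && phi < 1) {
      eps <- speckle_complex_field(bshape, psf_vox, 1)
      z <- list(re = phi * z$re + sqrt(1 - phi^2) * eps$re,
                im = phi * z$im + sqrt(1 - phi^2) * eps$im)
    }
    f <- static$data
    a <- sqrt(z$re^2 + z$im^2) * amp_scale
    box <- f[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    box[sub_inside] <- a[sub_inside]
    f[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- box
    frames[[i]] <- f
  }
  burst_stack(frames, g, timestamp = static$timestamp)
}

#' Analytic radial contraction displacement field
#'
#' The field of a contracting spherical inclusion of radius R: for r >= R,
#' `u(r) = -A (R/r)^p r_hat` (pointing toward the center, magnitude A at the
#' surface); inside the sphere the field ramps linearly,
#' `u(r) = -A (r/R) r_hat`. The field is curl-free outside the inclusion and
#' continuous at r = R.
#'
#' @param center center of contraction (um).
#' @param A surface displacement amplitude (um), >= 0.
#' @param R inclusion radius (um).
#' @param p far-field decay exponent (> 0); p = 2 matches an incompressible
#'   point-like contraction.
#' @param grid a [voxel_grid()].
#' @param timestamp minutes.
#' @return A [displacement_field()] in um.
#' @export
radial_contraction_field <- function(center, A, R, p, grid, timestamp = 0) {
  if (A < 0) stop("`A` must be >= 0")
  ext <- grid_extent(grid)
  if (any(center < grid$origin) || any(center > grid$origin + ext))
    stop("`center` lies outside the grid")
  cx <- (center - grid$origin) / grid$pitch
  X <- ((0:(grid$shape[1] - 1)) - cx[1]) * grid$pitch[1]
  Y <- ((0:(grid$shape[2] - 1)) - cx[2]) * grid$pitch[2]
  Z <- ((0:(grid$shape[3] - 1)) - cx[3]) * grid$pitch[3]
  r <- sqrt(outer(outer(X^2, Y^2, `+`), Z^2, `+`))
  mag <- ifelse(r >= R, A * (R / pmax(r, R))^p, A * r / R)
  scale <- ifelse(r > 0, -mag / r, 0)   # -u_hat scaling: u = scale * (x - c)
  ux <- scale * outer(outer(X, rep(1, grid$shape[2])), rep(1, grid$shape[3]))
  uy <- scale * outer(outer(rep(1, grid$shape[1]), Y), rep(1, grid$shape[3]))
  uz <- scale * outer(outer(rep(1, grid$shape[1]), rep(1, grid$shape[2])),
                      Z, function(a, b) a * b)
  displacement_field(ux, uy, uz, grid, timestamp = timestamp)
}

#' Warp a volume by a displacement field (pull-back)
#'
#' Resamples `volume` at `x + u(x)` (field in um, converted to voxels via the
#' grid pitch), the convention used by demons registration: warping the
#' moving image by the estimated field reproduces the fixed image. Samples
#' that fall outside the grid are set to 0 and flagged in the `"inside"`
#' attribute of the result.
#'
#' @param volume a [volume_image()].
#' @param field a [displacement_field()] on the same grid.
#' @param interpolation `"cubic"` (Catmull-Rom, default) or `"linear"`.
#' @return A [volume_image()]; `attr(, "inside")` is a 0/1 array marking
#'   in-domain samples.
#' @export
warp_volume <- function(volume, field, interpolation = c("cubic", "linear")) {
  interpolation <- match.arg(interpolation)
  g <- volume$grid
  if (!identical(g$shape, field$grid$shape)) stop("field grid mismatch")
  res <- cpp_warp3(volume$data, g$shape,
                   field$ux / g$pitch[1], field$uy / g$pitch[2],
                   field$uz / g$pitch[3],
                   interpolation == "cubic")
  out <- volume_image(res$data, g, role = volume$role,
                      timestamp = field$timestamp)
  attr(out, "inside") <- res$inside
  out
}

#' Generate a full synthetic burst-mode time-lapse with ground truth
#'
#' For each of `t_points` time-points: the t = 0 collagen speckle is warped
#' by the scheduled contraction field (linear amplitude ramp reaching
#' `contraction_A_um` at the last time-point), decorrelating cell speckle is
#' composited inside the (possibly grown) spheroid mask, the whole FOV is
#' translated by the cumulative stage drift, and the depth background plus
#' Gaussian amplitude noise are added.
#'
#' The ground-truth displacement field stored for each time-point is the
#' *pull-back* field actually used to synthesise the frame (see
#' [displacement_field()] for the sign convention); registration of the
#' t = 0 collagen onto time t recovers it directly.
#'
#' @param spec a [phantom_spec()].
#' @param t_points number of time-points (>= 1).
#' @param n_frames burst frames per time-point (default 8).
#' @return A list with `series` (a [timelapse_series()] of [burst_stack()]s)
#'   and `truth` (class `ground_truth`: `masks`, `fields`, `drift_um`,
#'   `drift_vox` (t x 2 matrices of cumulative drift), `background`,
#'   `collagen0`, and the noiseless drift-free `collagen` volumes per t).
#' @export
generate_timelapse <- function(spec, t_points, n_frames = 8L) {
  if (t_points < 1L) stop("`t_points` must be >= 1")
  g <- spec$grid
  collagen0 <- make_collagen_speckle(spec)
  max_drift_vox <- (t_points - 1) * abs(spec$drift_um_per_step) /
    g$pitch[1:2]
  if (any(max_drift_vox > 0.25 * g$shape[1:2]))
    stop("accumulated drift pushes the phantom off-grid")
  items <- vector("list", t_points)
  masks <- vector("list", t_points)
  fields <- vector("list", t_points)
  collagen_t <- vector("list", t_points)
  drift_um <- matrix(0, t_points, 2)
  A_end <- spec$contraction_A_um
  zero <- array(0, g$shape)      # shared by all zero fields (copy-on-write)
  mask0 <- make_spheroid_mask(spec, step = 0)
  for (k in seq_len(t_points)) {
    t_min <- (k - 1) * spec$interval_min
    A_k <- if (t_points == 1L) 0 else A_end * (k - 1) / (t_points - 1)
    if (A_k == 0) {
      gfield <- displacement_field(zero, zero, zero, g, timestamp = t_min)
      ck <- collagen0
    } else {
      u <- radial_contraction_field(spec$center_um, A_k, spec$radius_um,
                                    spec$contraction_p, g, timestamp = t_min)
      # pull-back field of an inward contraction points outward: negate
      gfield <- displacement_field(-u$ux, -u$uy, -u$uz, g, timestamp = t_min)
      ck <- warp_volume(collagen0, gfield)
      ck$data <- pmax(ck$data, 0)   # cubic interpolation can overshoot below 0
    }
    fields[[k]] <- gfield
    ck$timestamp <- t_min
    collagen_t[[k]] <- ck
    mk <- if (spec$growth_um_per_step == 0) mask0
          else make_spheroid_mask(spec, step = k - 1)
    mk$timestamp <- t_min
    masks[[k]] <- mk
    burst <- simulate_burst(ck, mk, spec$rho, n_frames,
                            seed = spec$seed + 1000L * k,
                            psf_sigma_um = spec$psf_sigma_um,
                            cell_gain = spec$cell_gain)
    drift_um[k, ] <- (k - 1) * spec$drift_um_per_step
    shift_vox <- c(drift_um[k, ] / g$pitch[1:2], 0)
    set.seed(spec$seed + 1000L * k + 500L)
    frames <- lapply(burst$volumes, function(f) {
      if (any(shift_vox != 0)) f <- pmax(fourier_shift3(f, shift_vox), 0)
      f <- f + rep(spec$background, each = g$shape[1] * g$shape[2])
      f <- f + array(stats::rnorm(length(f), sd = spec$noise_sd), dim(f))
      pmax(f, 0)
    })
    items[[k]] <- burst_stack(frames, g, timestamp = t_min)
  }
  truth <- structure(list(masks = masks, fields = fields,
                          drift_um = drift_um,
                          drift_vox = sweep(drift_um, 2, g$pitch[1:2], `/`),
                          background = spec$background,
                          collagen0 = collagen0, collagen = collagen_t,
                          spec = spec),
                     class = "ground_truth")
  list(series = timelapse_series(items, interval = spec$interval_min,
                                 duration = (t_points - 1) * spec$interval_min),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d time-points; max |field| %.3g um; final drift (%g, %g) um\n",
              length(x$masks),
              max(vapply(x$fields, function(f) max(field_magnitude(f)), numeric(1))),
              x$drift_um[nrow(x$drift_um), 1], x$drift_um[nrow(x$drift_um), 2]))
  invisible(x)
}
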