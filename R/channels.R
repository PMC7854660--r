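#' Burst projections: mean and temporal-speckle standard deviation
#'
#' `mean_projection()` is the per-voxel arithmetic mean of the N burst
#' amplitudes |S_i|; it averages speckle and serves as the basis of the
#' 'collagen' channel and of drift estimation. `std_projection()` is the
#' per-voxel sample standard deviation (1/(N-1) normalisation) of |S_i|
#' about that mean; temporally unstable speckle (live cells) lights up while
#' static collagen speckle cancels, which is what makes a label-free 'cell'
#' channel possible.
#'
#' Both are invariant to the ordering of burst frames and scale linearly
#' with a global amplitude rescaling.
#'
#' @param burst a [burst_stack()].
#' @return A [volume_image()] with role `mean_projection` /
#'   `std_projection`.
#' @export
mean_projection <- function(burst) {
  if (!inherits(burst, "burst_stack")) stop("`burst` must be a burst_stack")
  acc <- Reduce(`+`, burst$volumes)
  volume_image(acc / burst$N, burst$grid, role = "mean_projection",
               timestamp = burst$timestamp)
}

#' @rdname mean_projection
#' @export
std_projection <- function(burst) {
  if (!inherits(burst, "burst_stack")) stop("`burst` must be a burst_stack")
  if (burst$N < 2L)
    stop("std projection requires N >= 2 frames (sample variance is undefined at N = 1)")
  # deviations from the first frame: cancellation-safe, and exactly zero
  # wherever all frames agree (static speckle)
  ref <- burst$volumes[[1]]
  devs <- lapply(burst$volumes, function(v) v - ref)
  m <- Reduce(`+`, devs) / burst$N
  acc <- Reduce(`+`, lapply(devs, function(d) (d - m)^2))
  volume_image(sqrt(acc / (burst$N - 1)), burst$grid, role = "std_projection",
               timestamp = burst$timestamp)
}

#' Down-sample a volume to an isotropic grid
#'
#' Reduces the lateral sampling by `ratio[1]:ratio[2]` (default 768:400) and
#' resamples the axial dimension so the result is isotropic at the new
#' lateral pitch. With the protocol's lateral FOVs this yields the
#' (1.88 um)^3 and (2.34 um)^3 voxels of the monoculture and co-culture
#' settings. A Gaussian anti-alias prefilter (sigma = 0.5 sqrt(f^2 - 1)
#' voxels for a reduction factor f) precedes cubic interpolation, so the
#' down-sampling doubles as smoothing.
#'
#' @param volume a [volume_image()].
#' @param ratio length-2 numeric, lateral down-sampling ratio (old:new).
#' @return A [volume_image()] on the coarser isotropic grid.
#' @export
downsample_isotropic <- function(volume, ratio = c(768, 400)) {
  f_lat <- ratio[1] / ratio[2]
  if (f_lat <= 1) stop("`ratio` must down-sample (ratio > 1)")
  g <- volume$grid
  if (abs(g$pitch[1] - g$pitch[2]) > 1e-9)
    stop("lateral pitches must be equal before isotropic down-sampling")
  new_pitch <- g$pitch[1] * f_lat
  factors <- new_pitch / g$pitch                # per-axis reduction factor
  new_shape <- pmax(1L, as.integer(round(g$shape / factors)))
  if (any(new_shape < 2L))
    stop("down-sampled volume would have fewer than 2 voxels on an axis")
  sig <- ifelse(factors > 1, 0.5 * sqrt(factors^2 - 1), 0)
  data <- gauss_blur(volume$data, sig)
  data <- cpp_resize3(data, g$shape, new_shape, TRUE)
  # center of new voxel 0 sits at source voxel coordinate 0.5 * f - 0.5
  new_origin <- g$origin + (0.5 * g$shape / new_shape - 0.5) * g$pitch
  volume_image(data, voxel_grid(new_shape, pitch = rep(new_pitch, 3),
                                origin = new_origin),
               role = volume$role, timestamp = volume$timestamp)
}

#' Depth-dependent background profile from the lateral periphery
#'
#' The 'cell' channel carries a depth-dependent additive background. It is
#' estimated as the per-depth median amplitude over a peripheral frame of
#' the lateral FOV (outer `margin` fraction on each side), a region chosen
#' to exclude the spheroid body and the glass surface; the median makes the
#' estimate robust to stray bright structure.
#'
#' @param volume a [volume_image()].
#' @param margin fraction (< 0.5) of the lateral FOV on each side, or an
#'   integer voxel count >= 1.
#' @return An object of class `depth_profile` (fields `values`, length nz,
#'   and `grid`).
#' @export
estimate_depth_background <- function(volume, margin = 0.15) {
  g <- volume$grid
  m <- if (margin < 1) round(margin * g$shape[1:2]) else rep(as.integer(margin), 2)
  if (any(m < 1L) || any(2L * m >= g$shape[1:2]))
    stop("`margin` must leave a non-empty central region (margin < half the FOV)")
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  xi <- seq_len(nx); yi <- seq_len(ny)
  peripheral <- outer(xi <= m[1] | xi > nx - m[1], rep(TRUE, ny), `&`) |
                outer(rep(TRUE, nx), yi <= m[2] | yi > ny - m[2], `&`)
  vals <- vapply(seq_len(nz), function(k) {
    stats::median(volume$data[, , k][peripheral])
  }, numeric(1))
  structure(list(values = vals, grid = g), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> nz = %d, range [%.3g, %.3g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Subtract a depth background profile
#'
#' Per-depth subtraction of the estimated background, clamped at 0 (the data
#' are linear amplitudes, which are non-negative). The result is the
#' completed 'cell' channel.
#'
#' @param volume a [volume_image()].
#' @param profile a `depth_profile` from [estimate_depth_background()].
#' @return A [volume_image()] with role `cell_channel`.
#' @export
subtract_background <- function(volume, profile) {
  nz <- volume$grid$shape[3]
  if (length(profile$values) != nz)
    stop("profile length does not match the volume depth")
  nxy <- volume$grid$shape[1] * volume$grid$shape[2]
  out <- volume$data - rep(profile$values, each = nxy)
  volume_image(pmax(out, 0), volume$grid, role = "cell_channel",
               timestamp = volume$timestamp)
}

#' Depth-coded colour projection
#'
#' Assigns each depth a unique colour and takes the maximum-intensity
#' projection of each colour channel along depth, collapsing a volume into
#' a single 2D image in which colour encodes depth relative to the
#' `reference_z` plane (the palette is centered there).
#'
#' @param volume a [volume_image()].
#' @param reference_z 0-based reference depth index (defaults to the middle
#'   plane).
#' @param palette a function `n -> n colours`, as [grDevices::hcl.colors()].
#' @return An nx x ny x 3 array of RGB values in \[0, 1\].
#' @export
depth_coded_projection <- function(volume, reference_z = NULL,
                                   palette = function(n) grDevices::hcl.colors(n, "Spectral")) {
  nz <- volume$grid$shape[3]
  if (is.null(reference_z)) reference_z <- (nz - 1) %/% 2
  if (reference_z < 0 || reference_z > nz - 1) stop("`reference_z` out of range")
  cols <- palette(nz)
  # rotate the palette so the reference plane gets the palette center
  shift <- reference_z - (nz - 1) %/% 2
  if (shift != 0) cols <- cols[((seq_len(nz) - 1 + shift) %% nz) + 1]
  rgb <- t(grDevices::col2rgb(cols)) / 255
  vmax <- max(volume$data)
  v <- if (vmax > 0) volume$data / vmax else volume$data
  out <- array(0, c(volume$grid$shape[1:2], 3L))
  for (ch in 1:3) {
    acc <- v[, , 1] * rgb[1, ch]
    if (nz > 1) for (k in 2:nz) acc <- pmax(acc, v[, , k] * rgb[k, ch])
    out[, , ch] <- acc
  }
  out
}

#' Extract an en face (lateral) plane
#'
#' @param volume a [volume_image()].
#' @param z 0-based depth index (z = 0 is the first plane).
#' @return An nx x ny matrix.
#' @export
enface_slice <- function(volume, z) {
  nz <- volume$grid$shape[3]
  if (z < 0 || z > nz - 1) stop("`z` out of range [0, ", nz - 1, "]")
  volume$data[, , z + 1]
}

#' Plot a depth-coded projection
#'
#' @param rgb an nx x ny x 3 array from [depth_coded_projection()].
#' @param ... passed to [graphics::rasterImage()].
#' @export
plot_depth_coded <- function(rgb, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(rgb)[1] / dim(rgb)[2])
  # array is (x, y, colour); rasterImage wants rows = y from top
  img <- aperm(rgb, c(2, 1, 3))[dim(rgb)[2]:1, , , drop = FALSE]
  graphics::rasterImage(img, 0, 0, 1, 1, ...)
  invisible(NULL)
}
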