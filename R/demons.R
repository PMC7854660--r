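#' Demons registration parameters
#'
#' Parameters of the multi-resolution Thirion demons registration. The
#' defaults (3 pyramid levels, 100 iterations per level, accumulated-field
#' Gaussian smoothing sigma = 2 voxels) are the published settings of the
#' pipeline this package implements. `smoothing_sigma` is interpreted in
#' voxels of the processing grid at each pyramid level, matching the
#' semantics of the usual "accumulated field smoothing" parameter.
#'
#' @param pyramid_levels number of resolution levels (>= 1), coarsening by
#'   a factor 2 per level.
#' @param iterations_per_level demons iterations at each level (>= 1).
#' @param smoothing_sigma Gaussian sigma (voxels) applied to the accumulated
#'   displacement field after every iteration (>= 0).
#' @param symmetric use the mean of fixed and warped-moving gradients in the
#'   demons force (default) rather than the fixed gradient alone.
#' @return An object of class `demons_params`.
#' @export
demons_params <- function(pyramid_levels = 3L, iterations_per_level = 100L,
                          smoothing_sigma = 2, symmetric = TRUE) {
  if (pyramid_levels < 1L) stop("`pyramid_levels` must be >= 1")
  if (iterations_per_level < 1L) stop("`iterations_per_level` must be >= 1")
  if (smoothing_sigma < 0) stop("`smoothing_sigma` must be >= 0")
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 smoothing_sigma = smoothing_sigma,
                 symmetric = isTRUE(symmetric)),
            class = "demons_params")
}

# one image pyramid: list of arrays, finest first
build_pyramid <- function(data, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- data
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    d <- dim(prev)
    nd <- pmax(2L, as.integer(round(d / 2)))
    sm <- gauss_blur(prev, rep(1, 3))       # anti-alias before decimation
    pyr[[l + 1L]] <- cpp_resize3(sm, d, nd, FALSE)
  }
  pyr
}

#' Thirion demons deformable registration
#'
#' Estimates the displacement field that registers `moving` onto `fixed`:
#' resampling `moving` at `x + u(x)` approximates `fixed`. The classic
#' optical-flow-inspired demons force
#' `du = (M_w - F) grad / (|grad|^2 + (M_w - F)^2)` is applied at every
#' iteration and the accumulated field is Gaussian-smoothed with
#' `smoothing_sigma` (diffusion-like regularisation), inside a coarse-to-fine
#' pyramid (factor 2 per level); the field from each level, suitably
#' rescaled, seeds the next. Intensities are normalised jointly by their
#' common maximum before registration, so the result is invariant to a
#' global amplitude rescaling. No diffeomorphic constraint is imposed;
#' [jacobian_report()] quantifies folding if needed.
#'
#' @param fixed,moving [volume_image()]s on a common grid; both must be
#'   non-constant and finite.
#' @param params a [demons_params()].
#' @return A [displacement_field()] in um, timestamped from `fixed`.
#' @export
demons_register <- function(fixed, moving, params = demons_params()) {
  g <- fixed$grid
  if (!identical(g$shape, moving$grid$shape)) stop("grids differ")
  F0 <- fixed$data; M0 <- moving$data
  if (!all(is.finite(F0)) || !all(is.finite(M0))) stop("non-finite input")
  if (max(F0) == min(F0) || max(M0) == min(M0))
    stop("constant image: registration is undefined")
  scale <- max(max(F0), max(M0))
  F0 <- F0 / scale; M0 <- M0 / scale
  L <- params$pyramid_levels
  pf <- build_pyramid(F0, L)
  pm <- build_pyramid(M0, L)
  field <- NULL
  for (l in seq(L, 1)) {
    d <- dim(pf[[l]])
    if (is.null(field)) {
      field <- list(ux = array(0, d), uy = array(0, d), uz = array(0, d))
    } else {
      dprev <- dim(field$ux)
      ratio <- d / dprev
      field <- list(
        ux = cpp_resize3(field$ux, dprev, d, FALSE) * ratio[1],
        uy = cpp_resize3(field$uy, dprev, d, FALSE) * ratio[2],
        uz = cpp_resize3(field$uz, dprev, d, FALSE) * ratio[3])
    }
    field <- cpp_demons_level(pf[[l]], pm[[l]], d,
                              params$iterations_per_level,
                              params$smoothing_sigma,
                              field$ux, field$uy, field$uz,
                              params$symmetric)
  }
  displacement_field(field$ux * g$pitch[1], field$uy * g$pitch[2],
                     field$uz * g$pitch[3], g, timestamp = fixed$timestamp)
}

#' Track collagen deformation across a series
#'
#' Registers the t = 0 collagen channel (moving image) onto the collagen
#' channel of every later time-point (fixed image) up to `horizon_min`.
#' Deformations beyond the horizon are skipped with a message: once invasion
#' reshapes the matrix substantially, the small-deformation assumptions of
#' elastic registration no longer hold (the published protocol stops at
#' 24 h for this reason).
#'
#' @param collagen list of [volume_image()]s (drift-corrected collagen
#'   channels), time-ordered, t = 0 first.
#' @param params a [demons_params()].
#' @param horizon_min tracking horizon in minutes (default 1440 = 24 h).
#' @return A [timelapse_series()] of [displacement_field()]s, including the
#'   zero field at t = 0; empty (with a warning) if `horizon_min < 0` or no
#'   time-point falls inside the horizon.
#' @export
track_series <- function(collagen, params = demons_params(),
                         horizon_min = 1440) {
  items <- if (inherits(collagen, "timelapse_series")) collagen$items else collagen
  if (length(items) < 1L || items[[1]]$timestamp != 0)
    stop("series must start at t = 0")
  if (horizon_min <= 0) {
    warning("empty tracking output: horizon excludes every time-point")
    return(list())
  }
  g <- items[[1]]$grid
  fields <- list()
  zero <- array(0, g$shape)
  fields[[1]] <- displacement_field(zero, zero, zero, g, timestamp = 0)
  skipped <- 0L
  if (length(items) > 1L) for (t in 2:length(items)) {
    ts <- items[[t]]$timestamp
    if (ts > horizon_min) {
      skipped <- skipped + 1L
      next
    }
    fields[[length(fields) + 1L]] <- demons_register(items[[t]], items[[1]], params)
  }
  if (skipped > 0L)
    message(skipped, " time-point(s) beyond the ", horizon_min,
            "-min horizon skipped")
  timelapse_series(fields)
}

#' Displacement noise floor from static volume pairs
#'
#' Registers each pair of nominally static volumes and reports the median
#' over pairs of the median displacement magnitude over the analysis region
#' (the grid interior, excluding a border of one smoothing length where the
#' field is unconstrained). This is the smallest displacement the tracking
#' pipeline can be trusted to report; it is returned in um and as a
#' fraction of the (mean lateral) voxel pitch.
#'
#' @param pairs list of 2-element lists of [volume_image()]s.
#' @param params a [demons_params()].
#' @param border interior margin in voxels (default `3 * smoothing_sigma`).
#' @return A list with `floor_um`, `floor_frac_pitch` and the per-pair
#'   medians `per_pair_um`.
#' @export
estimate_noise_floor <- function(pairs, params = demons_params(),
                                 border = NULL) {
  if (length(pairs) < 1L) stop("need at least one pair")
  if (is.null(border)) border <- ceiling(3 * params$smoothing_sigma)
  med <- vapply(pairs, function(p) {
    f <- demons_register(p[[2]], p[[1]], params)
    m <- field_magnitude(f)
    d <- dim(m)
    b <- pmin(border, floor((d - 1) / 2))
    stats::median(m[(1 + b[1]):(d[1] - b[1]),
                    (1 + b[2]):(d[2] - b[2]),
                    (1 + b[3]):(d[3] - b[3])])
  }, numeric(1))
  g <- pairs[[1]][[1]]$grid
  floor_um <- stats::median(med)
  list(floor_um = floor_um,
       floor_frac_pitch = floor_um / mean(g$pitch[1:2]),
       per_pair_um = med)
}

#' Export a displacement field as an arrow table
#'
#' Subsamples the field on a regular stride, outside the cell mask (matrix
#' displacements inside or near the cell body are not reliable), in physical
#' units -- ready for quiver/cone rendering or CSV export.
#'
#' @param field a [displacement_field()].
#' @param mask optional binary [volume_image()]; voxels with mask = 1 are
#'   dropped.
#' @param stride voxel stride (>= 1) along each axis.
#' @return data.frame with columns x, y, z (um, voxel centers) and ux, uy,
#'   uz (um).
#' @export
export_arrows <- function(field, mask = NULL, stride = 1L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("`stride` must be >= 1")
  g <- field$grid
  xi <- seq(1L, g$shape[1], by = stride)
  yi <- seq(1L, g$shape[2], by = stride)
  zi <- seq(1L, g$shape[3], by = stride)
  idx <- as.matrix(expand.grid(x = xi, y = yi, z = zi))
  if (!is.null(mask)) {
    keep <- mask$data[idx] == 0
    idx <- idx[keep, , drop = FALSE]
  }
  data.frame(
    x = g$origin[1] + (idx[, 1] - 1) * g$pitch[1],
    y = g$origin[2] + (idx[, 2] - 1) * g$pitch[2],
    z = g$origin[3] + (idx[, 3] - 1) * g$pitch[3],
    ux = field$ux[idx], uy = field$uy[idx], uz = field$uz[idx]
  )
}

#' Fraction of folding (negative-Jacobian) voxels of a field
#'
#' Diagnostic for the non-diffeomorphic demons output: the fraction of
#' interior voxels where the Jacobian determinant of `x + u(x)` is negative
#' (the deformation folds space).
#'
#' @param field a [displacement_field()].
#' @return Scalar fraction in \[0, 1\].
#' @export
jacobian_report <- function(field) {
  g <- field$grid
  # components in voxel units for a dimensionless Jacobian
  ux <- field$ux / g$pitch[1]
  uy <- field$uy / g$pitch[2]
  uz <- field$uz / g$pitch[3]
  d <- dim(ux)
  ctr <- function(a, ax) {
    n <- d[ax]
    ip <- c(2:n, n); im <- c(1, 1:(n - 1))
    if (ax == 1) (a[ip, , ] - a[im, , ]) / 2
    else if (ax == 2) (a[, ip, ] - a[, im, ]) / 2
    else (a[, , ip] - a[, , im]) / 2
  }
  j11 <- 1 + ctr(ux, 1); j12 <- ctr(ux, 2); j13 <- ctr(ux, 3)
  j21 <- ctr(uy, 1); j22 <- 1 + ctr(uy, 2); j23 <- ctr(uy, 3)
  j31 <- ctr(uz, 1); j32 <- ctr(uz, 2); j33 <- 1 + ctr(uz, 3)
  det <- j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  mean(det < 0)
}
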