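#' Peripheral sub-volumes used for drift estimation
#'
#' Extracts four rectangular strips along the west, east, north and south
#' sides of the lateral FOV (full depth), excluding the central block where
#' the spheroid and the glass surface sit. The strips are pairwise disjoint:
#' the W/E strips take the full y range and the N/S strips are limited to
#' the central x range.
#'
#' @param volume a [volume_image()].
#' @param margin strip width as a fraction (< 0.5) of the lateral FOV; the
#'   default 0.25 excludes the central 50% x 50% block.
#' @return A named list of four [volume_image()]s (`west`, `east`, `north`,
#'   `south`); each carries its index ranges in attribute `"extent"`.
#' @export
extract_side_subvolumes <- function(volume, margin = 0.25) {
  g <- volume$grid
  nx <- g$shape[1]; ny <- g$shape[2]
  w <- round(margin * c(nx, ny))
  if (margin <= 0 || margin >= 0.5 || any(w < 1L) || any(2L * w >= c(nx, ny)))
    stop("`margin` must leave a non-empty central block (0 < margin < 0.5)")
  ranges <- list(
    west  = list(x = 1:w[1], y = 1:ny),
    east  = list(x = (nx - w[1] + 1):nx, y = 1:ny),
    north = list(x = (w[1] + 1):(nx - w[1]), y = 1:w[2]),
    south = list(x = (w[1] + 1):(nx - w[1]), y = (ny - w[2] + 1):ny)
  )
  lapply(ranges, function(r) {
    sub <- volume$data[r$x, r$y, , drop = FALSE]
    out <- volume_image(sub, voxel_grid(dim(sub), pitch = g$pitch,
                                        origin = g$origin +
                                          c(r$x[1] - 1, r$y[1] - 1, 0) * g$pitch),
                        role = volume$role, timestamp = volume$timestamp)
    attr(out, "extent") <- r
    out
  })
}

# upsampled cross-correlation in a window around `center` (voxel offsets)
# via matrix-multiply DFT; CP is the cross-power spectrum fft(mov)*Conj(fft(ref))
upsampled_xcorr_peak <- function(CP, center, upsample = 100, halfwidth = 1.5) {
  d <- dim(CP)
  nwin <- ceiling(halfwidth * upsample) * 2 + 1
  offs <- (seq_len(nwin) - 1 - (nwin - 1) / 2) / upsample
  mats <- lapply(1:3, function(ax) {
    k <- fft_freq_idx(d[ax])
    # rows: sample offsets around the coarse peak; cols: frequency bins
    exp(2i * pi * outer(center[ax] + offs, k) / d[ax])
  })
  # contract axis by axis: result[s1, s2, s3] = sum CP * ramps
  a <- CP
  dim(a) <- c(d[1], d[2] * d[3])
  a <- mats[[1]] %*% a                      # nwin x (d2*d3)
  dim(a) <- c(nwin, d[2], d[3])
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(d[2], nwin * d[3])
  a <- mats[[2]] %*% a                      # nwin x (nwin*d3)
  dim(a) <- c(nwin, nwin, d[3])
  a <- aperm(a, c(3, 1, 2))
  dim(a) <- c(d[3], nwin * nwin)
  a <- mats[[3]] %*% a                      # nwin x (nwin*nwin)
  dim(a) <- c(nwin, nwin, nwin)             # axes here are (s3, s2, s1)
  a <- aperm(a, c(3, 2, 1))
  peak <- which.max(abs(a))
  sub <- arrayInd(peak, dim(a))
  center + offs[sub]
}

#' Sub-pixel 3D shift between two volumes
#'
#' Estimates the translation of `moving` relative to `reference` by the peak
#' of their 3D cross-correlation, refined to sub-pixel precision by local
#' Fourier up-sampling (matrix-multiply DFT; default factor 100, i.e.
#' 0.01-voxel precision). The returned shift `s` satisfies
#' `moving(x) ~ reference(x - s)`: content that moved by +s gives +s.
#'
#' Two de-biasing steps precede the correlation. The laterally-uniform
#' component of each volume (the per-depth-plane mean) is removed, because a
#' static additive depth background does not translate with the sample and
#' drags the peak toward zero. And a `margin`-voxel border of the *moving*
#' volume is zeroed, so that every retained voxel has a matching partner in
#' the reference for any lag up to `margin`: the overlap envelope of the
#' finite window is then flat around the peak instead of biasing it toward
#' smaller shifts.
#'
#' @param reference,moving [volume_image()]s (or bare 3D arrays) on a common
#'   grid.
#' @param upsample sub-pixel refinement factor.
#' @param margin zeroed border of the moving volume, voxels (shrunk on tiny
#'   inputs); estimates are unbiased for shifts up to this size.
#' @return Numeric length-3 shift (dx, dy, dz) in voxels.
#' @export
estimate_shift_3d <- function(reference, moving, upsample = 100, margin = 4L) {
  a <- if (inherits(reference, "volume_image")) reference$data else reference
  b <- if (inherits(moving, "volume_image")) moving$data else moving
  if (!identical(dim(a), dim(b))) stop("volumes must share a grid")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("flat (zero-variance) volume: shift is undefined")
  demean <- function(v) v - rep(colMeans(v, dims = 2), each = dim(v)[1] * dim(v)[2])
  a <- demean(a); b <- demean(b)
  d <- dim(a)
  m <- pmin(as.integer(margin), (d - 1L) %/% 4L)
  if (any(m > 0L)) {
    keep <- array(0, d)
    keep[(1 + m[1]):(d[1] - m[1]), (1 + m[2]):(d[2] - m[2]),
         (1 + m[3]):(d[3] - m[3])] <- 1
    b <- b * keep
  }
  CP <- stats::fft(b) * Conj(stats::fft(a))
  corr <- Re(stats::fft(CP, inverse = TRUE))
  peak <- arrayInd(which.max(corr), d) - 1L
  peak <- ifelse(peak > d / 2, peak - d, peak)   # signed integer shift
  if (upsample <= 1) return(as.numeric(peak))
  # coarse-to-fine local refinement keeps the upsampled DFT windows small
  est <- upsampled_xcorr_peak(CP, as.numeric(peak), upsample = 10,
                              halfwidth = 0.75)
  if (upsample > 10)
    est <- upsampled_xcorr_peak(CP, est, upsample = upsample,
                                halfwidth = 1.5 / 10)
  est
}

#' Drift record
#'
#' Per-time-point lateral drift estimate: the step shift relative to the
#' previous time-point, the cumulative shift relative to t = 0 (running sum
#' of steps), and the raw per-strip estimates (including the axial
#' component, which is reported for diagnostics but never used for
#' correction -- axial drift is handled upstream of this pipeline).
#'
#' @param timestamp minutes.
#' @param step_shift (dx, dy) voxels relative to the previous time-point.
#' @param cumulative_shift (dx, dy) voxels relative to t = 0.
#' @param raw matrix of per-strip (dx, dy, dz) estimates.
#' @return An object of class `drift_record`.
#' @export
drift_record <- function(timestamp, step_shift, cumulative_shift,
                         raw = matrix(0, 0, 3)) {
  structure(list(timestamp = timestamp,
                 step_shift = as.numeric(step_shift),
                 cumulative_shift = as.numeric(cumulative_shift),
                 raw = raw),
            class = "drift_record")
}

#' @export
print.drift_record <- function(x, ...) {
  cat(sprintf("<drift_record t=%g min> step (%.3f, %.3f) vox, cum (%.3f, %.3f) vox\n",
              x$timestamp, x$step_shift[1], x$step_shift[2],
              x$cumulative_shift[1], x$cumulative_shift[2]))
  invisible(x)
}

#' Estimate the lateral drift trace of a series
#'
#' For every time-point after the first, the four peripheral strips (see
#' [extract_side_subvolumes()]) are cross-correlated against the same strips
#' of the *previous* time-point; the step drift is the component-wise median
#' of the four sub-volume estimates (with four values, the mean of the two
#' central ones), and the cumulative drift is the running sum of steps from
#' t = 0. Only the lateral (x, y) components are retained for correction. A
#' strip whose estimate fails is dropped; at least two surviving strips are
#' required.
#'
#' @param volumes list of [volume_image()]s (typically mean projections),
#'   time-ordered.
#' @param margin strip width fraction, as in [extract_side_subvolumes()].
#' @param upsample sub-pixel refinement factor.
#' @return A list of [drift_record()]s, one per time-point (the first is
#'   zero).
#' @export
lateral_drift_series <- function(volumes, margin = 0.25, upsample = 100) {
  if (length(volumes) < 2L) stop("need at least two time-points")
  records <- vector("list", length(volumes))
  records[[1]] <- drift_record(volumes[[1]]$timestamp, c(0, 0), c(0, 0))
  prev <- extract_side_subvolumes(volumes[[1]], margin)
  cum <- c(0, 0)
  for (t in 2:length(volumes)) {
    cur <- extract_side_subvolumes(volumes[[t]], margin)
    raw <- matrix(NA_real_, 4, 3,
                  dimnames = list(names(cur), c("dx", "dy", "dz")))
    for (s in seq_along(cur)) {
      est <- tryCatch(estimate_shift_3d(prev[[s]], cur[[s]], upsample),
                      error = function(e) NULL)
      if (!is.null(est)) raw[s, ] <- est
    }
    ok <- stats::complete.cases(raw)
    if (sum(ok) < 2L)
      stop("fewer than two usable drift strips at t = ", volumes[[t]]$timestamp)
    step <- apply(raw[ok, 1:2, drop = FALSE], 2, stats::median)
    cum <- cum + step
    records[[t]] <- drift_record(volumes[[t]]$timestamp, step, cum, raw)
    prev <- cur
  }
  records
}

#' Remove estimated drift from a series
#'
#' Translates every volume (or every burst frame) at time t by the negative
#' cumulative lateral shift via a spectral phase ramp -- exact sub-pixel
#' translation for band-limited data, no resampling blur. The circularly
#' wrapped border columns are zero-filled.
#'
#' @param series a [timelapse_series()] of [volume_image()]s or
#'   [burst_stack()]s, or a plain list of them.
#' @param records list of [drift_record()]s, one per time-point.
#' @return The corrected series, same container type as the input.
#' @export
correct_drift <- function(series, records) {
  items <- if (inherits(series, "timelapse_series")) series$items else series
  if (length(items) != length(records))
    stop("records and series differ in length")
  fix_vol <- function(v, cum) {
    if (all(cum == 0)) return(v)
    sh <- c(-cum[1], -cum[2], 0)
    out <- pmax(fourier_shift3(v, sh), 0)
    zero_wrapped_border(out, sh)
  }
  out <- mapply(function(item, rec) {
    cum <- rec$cumulative_shift
    if (inherits(item, "burst_stack")) {
      burst_stack(lapply(item$volumes, fix_vol, cum = cum), item$grid,
                  timestamp = item$timestamp)
    } else {
      volume_image(fix_vol(item$data, cum), item$grid, role = item$role,
                   timestamp = item$timestamp)
    }
  }, items, records, SIMPLIFY = FALSE)
  if (inherits(series, "timelapse_series"))
    timelapse_series(out, interval = series$interval, duration = series$duration)
  else out
}

#' Drift trace as a data frame
#'
#' @param records list of [drift_record()]s.
#' @param pitch_um lateral pitch (um) used to add physical columns.
#' @return data.frame with columns t_min, step_dx, step_dy, cum_dx, cum_dy
#'   (voxels) and cum_dx_um, cum_dy_um.
#' @export
drift_table <- function(records, pitch_um = c(1, 1)) {
  data.frame(
    t_min = vapply(records, `[[`, numeric(1), "timestamp"),
    step_dx = vapply(records, function(r) r$step_shift[1], numeric(1)),
    step_dy = vapply(records, function(r) r$step_shift[2], numeric(1)),
    cum_dx = vapply(records, function(r) r$cumulative_shift[1], numeric(1)),
    cum_dy = vapply(records, function(r) r$cumulative_shift[2], numeric(1)),
    cum_dx_um = vapply(records, function(r) r$cumulative_shift[1], numeric(1)) * pitch_um[1],
    cum_dy_um = vapply(records, function(r) r$cumulative_shift[2], numeric(1)) * pitch_um[2]
  )
}
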