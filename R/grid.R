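#' Physical voxel grid
#'
#' A voxel grid describes the sampling of a 3D volume on a physical coordinate
#' system. Axes are ordered (x, y, z) with z the depth axis (increasing away
#' from the objective). Voxel indices are 0-based in all coordinate formulas;
#' the physical coordinate of a voxel is the coordinate of its *center*, so
#' voxel (0, 0, 0) sits at `origin` and voxel (i, j, k) at
#' `origin + c(i, j, k) * pitch`.
#'
#' @param shape integer vector of length 3, voxels per axis (nx, ny, nz).
#' @param pitch numeric vector of length 3 (or a scalar, recycled), voxel
#'   spacing per axis in micrometres.
#' @param origin physical coordinate (um) of the center of voxel (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(128, 128, 96), pitch = 1.88)
#' grid_extent(g)   # physical extent in um
#' @export
voxel_grid <- function(shape, pitch = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three integers >= 1")
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("`pitch` must be three positive spacings (um)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 coordinate (um)")
  structure(list(shape = shape, pitch = pitch, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
grid_extent <- function(grid) grid$shape * grid$pitch

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, pitch (%g, %g, %g) um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$pitch[1], x$pitch[2], x$pitch[3]))
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.voxel_grid <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$pitch - b$pitch) <= tol * pmax(1, abs(a$pitch))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin), abs(b$origin)))
}

#' Single scalar volume on a voxel grid
#'
#' The basic image container: a 3D numeric array plus its [voxel_grid()],
#' a role tag describing what the volume holds, and an acquisition timestamp
#' in minutes. Roles used by the pipeline are `"mean_projection"` and
#' `"std_projection"` (burst statistics), `"cell_channel"`,
#' `"collagen_channel"` and `"binary_mask"`; `"raw"` marks anything else.
#'
#' Binary masks must contain only 0/1 values. A collagen channel is by
#' construction zero wherever its paired cell mask is 1 (see
#' [make_collagen_channel()]).
#'
#' @param data numeric 3D array, dimensions matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @param role character role tag.
#' @param timestamp acquisition time in minutes.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, grid, role = "raw", timestamp = 0) {
  roles <- c("raw", "mean_projection", "std_projection", "cell_channel",
             "collagen_channel", "binary_mask")
  role <- match.arg(role, roles)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("`data` dimensions do not match grid shape")
  if (!all(is.finite(data)))
    stop("`data` must be finite")
  if (role == "binary_mask" && !all(data %in% c(0, 1)))
    stop("binary_mask values must be 0 or 1")
  structure(list(data = data, grid = grid, role = role,
                 timestamp = as.numeric(timestamp)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image role=%s t=%g min> ", x$role, x$timestamp))
  print(x$grid)
  invisible(x)
}

#' Burst of co-registered volumes at one time-point
#'
#' One time-point of the burst acquisition protocol: N amplitude volumes
#' acquired in rapid succession on a common grid (the protocol this package
#' models acquires N = 8 reduced-field-of-view volumes
#' per burst). Amplitudes are stored linear and non-negative; all burst
#' statistics operate on |S|.
#'
#' @param volumes list of N numeric 3D arrays (or `volume_image`s) sharing
#'   one grid.
#' @param grid a [voxel_grid()] (taken from the first volume if omitted and
#'   volumes are `volume_image`s).
#' @param timestamp acquisition time in minutes.
#' @return An object of class `burst_stack`.
#' @export
burst_stack <- function(volumes, grid = NULL, timestamp = 0) {
  if (length(volumes) < 1L) stop("burst must contain at least one volume")
  vols <- lapply(volumes, function(v) {
    if (inherits(v, "volume_image")) {
      if (is.null(grid)) grid <<- v$grid
      v$data
    } else v
  })
  if (is.null(grid)) stop("`grid` required when volumes are bare arrays")
  for (v in vols) {
    if (!identical(as.integer(dim(v)), grid$shape))
      stop("all burst volumes must share the grid shape")
    if (any(v < 0)) stop("burst amplitudes must be non-negative (store |S|)")
  }
  structure(list(volumes = vols, grid = grid, N = length(vols),
                 timestamp = as.numeric(timestamp)),
            class = "burst_stack")
}

#' @export
print.burst_stack <- function(x, ...) {
  cat(sprintf("<burst_stack N=%d t=%g min> ", x$N, x$timestamp))
  print(x$grid)
  invisible(x)
}

#' 3D displacement field
#'
#' Three component volumes (u_x, u_y, u_z) on a [voxel_grid()], in
#' micrometres. The stored field is the *pull-back* (registration) field
#' mapping the t = 0 image onto the time-t image: resampling the t = 0
#' volume at `x + u(x)` reproduces the time-t volume. This is exactly the
#' field estimated by [demons_register()] with `fixed` the time-t image and
#' `moving` the t = 0 image. The physical displacement of the material is
#' `-u` evaluated at the corresponding point, to first order in `|u|`.
#'
#' @param ux,uy,uz numeric 3D arrays of the field components, in um.
#' @param grid a [voxel_grid()].
#' @param timestamp time in minutes of the target image.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(ux, uy, uz, grid, timestamp = 0) {
  for (comp in list(ux, uy, uz)) {
    if (!identical(as.integer(dim(comp)), grid$shape))
      stop("field component dimensions do not match grid shape")
    if (!all(is.finite(comp))) stop("field must be finite")
  }
  structure(list(ux = ux, uy = uy, uz = uz, grid = grid,
                 timestamp = as.numeric(timestamp)),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @param field a `displacement_field`.
#' @return `field_magnitude()`: 3D array of |u| in um.
#' @export
field_magnitude <- function(field) {
  sqrt(field$ux^2 + field$uy^2 + field$uz^2)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- field_magnitude(x)
  cat(sprintf("<displacement_field t=%g min, |u| max %.3g um> ",
              x$timestamp, max(m)))
  print(x$grid)
  invisible(x)
}

#' Time-lapse series
#'
#' An ordered sequence of per-time-point payloads ([burst_stack()],
#' [volume_image()], [displacement_field()] or drift records) with strictly
#' increasing timestamps starting at 0. The nominal cadence of the imaging
#' protocol is 40 minutes over 48 h; deviations are tolerated and carried
#' through.
#'
#' @param items list of payloads, each carrying a `timestamp` field
#'   (minutes).
#' @param interval nominal cadence in minutes.
#' @param duration nominal total span in minutes.
#' @return An object of class `timelapse_series`.
#' @export
timelapse_series <- function(items, interval = 40, duration = 2880) {
  ts <- vapply(items, function(x) x$timestamp, numeric(1))
  if (length(ts) == 0L) stop("series must contain at least one item")
  if (ts[1] != 0) stop("first timestamp must be 0")
  if (length(ts) > 1L && any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(items = items, timestamps = ts,
                 interval = interval, duration = duration),
            class = "timelapse_series")
}

#' @export
length.timelapse_series <- function(x) length(x$items)

#' @export
print.timelapse_series <- function(x, ...) {
  cat(sprintf("<timelapse_series> %d time-points, t = %g .. %g min (cadence %g min)\n",
              length(x$items), x$timestamps[1],
              x$timestamps[length(x$timestamps)], x$interval))
  invisible(x)
}

# internal: fetch payload at index i (1-based)
series_item <- function(series, i) series$items[[i]]
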