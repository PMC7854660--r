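#' Optical layout of the scanning relay
#'
#' The sample-arm relay images a galvanometer mirror pair (separated by
#' `d` mm along the optical axis) to the objective back focal plane through
#' a 1:1 4F telescope of two `f` mm lenses. The mirror separation produces
#' coherence gate curvature (CGC), compensated by a central cylindrical
#' lens.
#'
#' @param f relay lens focal length, mm (default 100).
#' @param d galvanometer mirror separation, mm (default 13.69).
#' @param f_y cylindrical lens focal length actually installed, mm
#'   (informational; the nearest off-the-shelf part to the design rule).
#' @return An object of class `optical_layout`.
#' @export
optical_layout <- function(f = 100, d = 13.69, f_y = 700) {
  if (f <= 0) stop("`f` must be > 0")
  if (d < 0) stop("`d` must be >= 0")
  structure(list(f = f, d = d, f_y = f_y), class = "optical_layout")
}

#' Design rule for the CGC-compensating cylindrical lens
#'
#' The optimal focal length of the compensating cylindrical lens is
#' `f^2 / d`: with the default relay (f = 100 mm) and mirror separation
#' (d = 13.69 mm) this gives ~730 mm, for which a +700 mm part is the
#' nearest stock lens. The rule is homogeneous of degree 2 in f.
#'
#' @param layout an [optical_layout()].
#' @return Focal length in mm.
#' @export
optimal_cylindrical_focal_length <- function(layout = optical_layout()) {
  if (layout$d == 0)
    stop("d = 0: no coherence gate curvature to compensate (focal length diverges)")
  layout$f^2 / layout$d
}

#' Acquisition plan for one time-lapse series
#'
#' Raw-data accounting inputs: per burst, 1 full-FOV volume (1024 x 1024
#' lateral samples) plus 8 reduced-FOV volumes (768 x 768), each A-scan a
#' 2048-sample spectrum at 2 bytes per sample; bursts every 40 min for 48 h.
#'
#' @param full_lateral,reduced_lateral lateral samples per axis.
#' @param n_reduced reduced-FOV volumes per burst.
#' @param spectral_samples samples per A-scan.
#' @param bytes_per_sample bytes per raw sample.
#' @param interval_min,duration_min cadence and total span, minutes.
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(full_lateral = 1024L, reduced_lateral = 768L,
                             n_reduced = 8L, spectral_samples = 2048L,
                             bytes_per_sample = 2L, interval_min = 40L,
                             duration_min = 2880L) {
  vals <- c(full_lateral, reduced_lateral, n_reduced, spectral_samples,
            bytes_per_sample, interval_min, duration_min)
  if (any(vals != as.integer(vals)) || any(vals < 0))
    stop("plan fields must be non-negative integers")
  structure(list(full_lateral = full_lateral, reduced_lateral = reduced_lateral,
                 n_reduced = n_reduced, spectral_samples = spectral_samples,
                 bytes_per_sample = bytes_per_sample,
                 interval_min = interval_min, duration_min = duration_min),
            class = "acquisition_plan")
}

#' Raw data volume of one burst
#'
#' `(full^2 + n_reduced * reduced^2) * spectral * bytes / 1e9` decimal
#' gigabytes; the default plan gives 23.62 GB, i.e. 24 GB to the nearest
#' integer.
#'
#' @param plan an [acquisition_plan()].
#' @return A list with `gb` (decimal GB) and `gb_nearest` (nearest integer).
#' @export
burst_raw_gigabytes <- function(plan = acquisition_plan()) {
  bytes <- (plan$full_lateral^2 + plan$n_reduced * plan$reduced_lateral^2) *
    plan$spectral_samples * plan$bytes_per_sample
  gb <- bytes / 1e9
  list(gb = gb, gb_nearest = round(gb))
}

#' Raw data volume of one time-lapse series
#'
#' Time-points = duration / interval + 1 (including t = 0; 73 for 48 h at
#' 40 min). Series size is the nominal (nearest-integer) per-burst GB times
#' the number of time-points, in decimal terabytes: 24 GB x 73 / 1000 =
#' 1.752 TB for the default plan.
#'
#' @param plan an [acquisition_plan()].
#' @return A list with `tb` (decimal TB), `time_points` and `gb_per_burst`.
#' @export
series_raw_terabytes <- function(plan = acquisition_plan()) {
  if (plan$interval_min <= 0) stop("`interval_min` must be > 0")
  if (plan$duration_min %% plan$interval_min != 0) {
    warning("duration is not a multiple of the interval; flooring")
  }
  tp <- plan$duration_min %/% plan$interval_min + 1
  gb <- burst_raw_gigabytes(plan)$gb_nearest
  list(tb = gb * tp / 1000, time_points = tp, gb_per_burst = gb)
}
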