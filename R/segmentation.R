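#' Cube median filter
#'
#' Per-voxel median over a `size^3` neighbourhood (default 5 x 5 x 5),
#' with reflecting boundary handling. Run on the 'cell' channel before
#' thresholding to suppress residual speckle grain.
#'
#' @param volume a [volume_image()].
#' @param size odd cube width in voxels.
#' @return A filtered [volume_image()].
#' @export
median_filter_3d <- function(volume, size = 5L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("`size` must be odd and >= 1")
  out <- cpp_median3(volume$data, volume$grid$shape, size)
  volume_image(out, volume$grid, role = volume$role,
               timestamp = volume$timestamp)
}

#' Otsu threshold of a volume
#'
#' Maximises the between-class variance over a `bins`-bin histogram spanning
#' \[0, max\] and returns the threshold together with the binary mask
#' `volume > threshold`. Errors on a constant volume (no separable classes).
#'
#' @param volume a [volume_image()].
#' @param bins number of histogram bins (default 256).
#' @return A list with `threshold` (amplitude units) and `mask`
#'   (a binary [volume_image()]).
#' @export
otsu_threshold <- function(volume, bins = 256L) {
  x <- volume$data
  vmax <- max(x)
  if (vmax <= min(x)) stop("constant volume: Otsu threshold is undefined")
  edges <- seq(0, vmax, length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins),
                nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)                      # class-0 probability up to bin k
  mu <- cumsum(p * seq_len(bins))         # first moment (bin index units)
  mu_t <- mu[bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # several bins can tie (e.g. an empty gap between modes): take the mean of
  # the maximising bin edges, the convention of the common implementations
  kset <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  thr <- mean(edges[kset + 1L])           # upper edge(s) of class-0's last bin
  mask <- volume_image(array(as.numeric(x > thr), dim(x)), volume$grid,
                       role = "binary_mask", timestamp = volume$timestamp)
  list(threshold = thr, mask = mask)
}

#' Largest 26-connected component
#'
#' Labels the binary mask with 26-connectivity (faces, edges and corners
#' adjacent) and keeps only the component with the largest voxel count. An
#' empty mask passes through unchanged. Ties are broken in favour of the
#' component whose first voxel comes earliest in column-major (x fastest,
#' then y, then z) scan order.
#'
#' @param mask a binary [volume_image()].
#' @return A binary [volume_image()] containing at most one component.
#' @export
largest_component <- function(mask) {
  lab <- cpp_label3(as.integer(mask$data != 0), mask$grid$shape)
  n <- max(lab)
  if (n == 0L)
    return(volume_image(array(0, mask$grid$shape), mask$grid,
                        role = "binary_mask", timestamp = mask$timestamp))
  counts <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(counts)               # which.max returns the first max
  volume_image(array(as.numeric(lab == keep), mask$grid$shape), mask$grid,
               role = "binary_mask", timestamp = mask$timestamp)
}

#' 4D region growing over a time-lapse of preliminary masks
#'
#' Cleans preliminary per-time-point segmentations by temporal consistency.
#' At t = 0 only the largest connected structure (the spheroid body) is
#' retained. For each later time-point, a connected component of the
#' preliminary mask is retained iff it shares at least one voxel with the
#' cleaned mask of the previous time-point; the cleaned mask then seeds the
#' next time-point. The rule is applied literally (no dilation of the seed),
#' so a cell that detaches and moves more than its own footprint between
#' time-points is lost -- the price of the rule's simplicity.
#'
#' @param preliminary list of binary [volume_image()]s, time-ordered.
#' @return An object of class `mask_series` with fields `preliminary` and
#'   `cleaned` (parallel lists of binary [volume_image()]s).
#' @export
region_grow_4d <- function(preliminary) {
  if (length(preliminary) < 1L) stop("need at least one time-point")
  cleaned <- vector("list", length(preliminary))
  cleaned[[1]] <- largest_component(preliminary[[1]])
  if (length(preliminary) > 1L) {
    for (t in 2:length(preliminary)) {
      pre <- preliminary[[t]]
      lab <- cpp_label3(as.integer(pre$data != 0), pre$grid$shape)
      n <- max(lab)
      keepmask <- array(0, pre$grid$shape)
      if (n > 0L) {
        seed <- cleaned[[t - 1]]$data != 0
        touching <- unique(lab[seed & lab > 0L])
        if (length(touching) > 0L)
          keepmask[lab %in% touching] <- 1
      }
      cleaned[[t]] <- volume_image(keepmask, pre$grid, role = "binary_mask",
                                   timestamp = pre$timestamp)
    }
  }
  structure(list(preliminary = preliminary, cleaned = cleaned),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  v <- vapply(x$cleaned, function(m) sum(m$data), numeric(1))
  cat(sprintf("<mask_series> %d time-points, cleaned voxels %s\n",
              length(x$cleaned), paste(v, collapse = ", ")))
  invisible(x)
}

#' Derive the 'collagen' channel
#'
#' The collagen channel is the (down-sampled) mean projection with every
#' voxel of the cleaned cell mask set to 0, leaving only static scatterers.
#'
#' @param mean_volumes list of [volume_image()]s (down-sampled mean
#'   projections), time-ordered and on the mask grid.
#' @param masks a `mask_series` from [region_grow_4d()], or a list of binary
#'   [volume_image()]s.
#' @return A list of [volume_image()]s with role `collagen_channel`.
#' @export
make_collagen_channel <- function(mean_volumes, masks) {
  cleaned <- if (inherits(masks, "mask_series")) masks$cleaned else masks
  if (length(mean_volumes) != length(cleaned))
    stop("mean volumes and masks differ in length")
  mapply(function(mv, mk) {
    if (!identical(mv$grid$shape, mk$grid$shape))
      stop("mean volume and mask grids differ")
    d <- mv$data
    d[mk$data != 0] <- 0
    volume_image(d, mv$grid, role = "collagen_channel",
                 timestamp = mv$timestamp)
  }, mean_volumes, cleaned, SIMPLIFY = FALSE)
}
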