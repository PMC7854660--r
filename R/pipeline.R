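#' Run the full processing pipeline
#'
#' Orchestrates the stages in the order of the acquisition protocol they
#' model: burst projections, lateral drift estimation and correction (on the
#' full-resolution mean projections), isotropic down-sampling, depth
#' background removal ('cell' channel), median + Otsu + 4D region-growing
#' segmentation, 'collagen' channel synthesis, and demons displacement
#' tracking up to the configured horizon.
#'
#' With `input = "simulate"` a synthetic phantom with full ground truth is
#' generated and every stage output is validated against it (drift error,
#' per-time-point Dice, displacement-field RMSE); otherwise `input` is a
#' path to an `"rds"` series of [burst_stack()]s.
#'
#' @param config a [pipeline_config()].
#' @param input `"simulate"` or a path readable by [read_series()].
#' @param phantom optional [phantom_spec()] overriding the default phantom
#'   (simulation only).
#' @param t_points number of simulated time-points.
#' @param track run the (comparatively slow) displacement tracking stage.
#' @param out_dir optional directory; stage products are written there as
#'   RDS and listed (with MD5 hashes) in the manifest.
#' @return An object of class `run_manifest`: config, seed, stage `timings`
#'   (seconds), `products` (in-memory results), `outputs` (paths + hashes),
#'   and `report` (ground-truth validation, simulation only).
#' @export
run_pipeline <- function(config = pipeline_config(), input = "simulate",
                         phantom = NULL, t_points = 6L, track = TRUE,
                         out_dir = NULL) {
  timings <- c()
  products <- list()
  outputs <- data.frame(stage = character(), path = character(),
                        md5 = character())
  persist <- function(name, obj) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    p <- file.path(out_dir, paste0(name, ".rds"))
    saveRDS(obj, p)
    outputs <<- rbind(outputs, data.frame(stage = name, path = p,
                                          md5 = unname(tools::md5sum(p))))
    invisible(p)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[name] <<- proc.time()[["elapsed"]] - t0
    res
  }

  truth <- NULL
  sim <- stage("input", {
    if (identical(input, "simulate")) {
      spec <- if (is.null(phantom))
        phantom_spec(seed = config$seed, interval_min = config$interval_min)
      else phantom
      generate_timelapse(spec, t_points, n_frames = config$burst_n)
    } else {
      list(series = read_series(input), truth = NULL)
    }
  })
  series <- sim$series
  truth <- sim$truth
  tstamps <- series$timestamps

  proj <- stage("projections", {
    list(mean = lapply(series$items, mean_projection),
         std = lapply(series$items, std_projection))
  })

  drift <- stage("drift", {
    if (length(proj$mean) >= 2L)
      lateral_drift_series(proj$mean, margin = config$drift_margin)
    else
      list(drift_record(tstamps[1], c(0, 0), c(0, 0)))
  })
  products$drift <- drift
  persist("drift", drift)

  corrected <- stage("drift_correct", {
    list(mean = correct_drift(proj$mean, drift),
         std = correct_drift(proj$std, drift))
  })

  ds <- stage("downsample", {
    list(mean = lapply(corrected$mean, downsample_isotropic,
                       ratio = config$downsample_ratio),
         std = lapply(corrected$std, downsample_isotropic,
                      ratio = config$downsample_ratio))
  })

  cells <- stage("background", {
    lapply(ds$std, function(v) {
      prof <- estimate_depth_background(v, margin = config$periphery_margin)
      subtract_background(v, prof)
    })
  })
  products$cell_channel <- cells
  persist("cell_channel", cells)

  masks <- stage("segmentation", {
    prelim <- lapply(cells, function(v)
      otsu_threshold(median_filter_3d(v, config$median_size))$mask)
    region_grow_4d(prelim)
  })
  products$masks <- masks
  persist("masks", masks)

  collagen <- stage("collagen_channel", {
    make_collagen_channel(ds$mean, masks)
  })
  products$collagen <- collagen
  persist("collagen", collagen)

  fields <- NULL
  if (track && length(collagen) > 1L) {
    fields <- stage("tracking", {
      track_series(collagen, params = config$demons,
                   horizon_min = config$tracking_horizon_min)
    })
    products$fields <- fields
    persist("fields", fields)
  }

  report <- NULL
  if (!is.null(truth)) {
    report <- stage("validation", {
      validate_against_truth(truth, drift, masks, collagen, fields)
    })
    persist("report", report)
  }

  structure(list(config = config, seed = config$seed, timings = timings,
                 products = products, outputs = outputs, report = report,
                 timestamps = tstamps,
                 version = as.character(utils::packageVersion("speckle4d"))),
            class = "run_manifest")
}

# resample a ground-truth array (sim grid) onto a processing grid
resample_to_grid <- function(data, from_grid, to_grid) {
  cpp_resize3(data, from_grid$shape, to_grid$shape, FALSE)
}

validate_against_truth <- function(truth, drift, masks, collagen, fields) {
  g <- truth$spec$grid
  T_n <- length(truth$masks)
  # drift: estimated cumulative vs true cumulative, voxels
  est_cum <- t(vapply(drift, `[[`, numeric(2), "cumulative_shift"))
  drift_err <- abs(est_cum - truth$drift_vox[seq_len(nrow(est_cum)), , drop = FALSE])
  # Dice on the processing grid
  gd <- masks$cleaned[[1]]$grid
  dice <- vapply(seq_len(T_n), function(k) {
    tm <- resample_to_grid(truth$masks[[k]]$data, g, gd) > 0.5
    dice_coefficient(tm, masks$cleaned[[k]]$data != 0)
  }, numeric(1))
  # collagen channel must vanish on the mask
  collagen_on_mask <- vapply(seq_len(T_n), function(k)
    max(abs(collagen[[k]]$data[masks$cleaned[[k]]$data != 0])), numeric(1))
  # field RMSE (voxels of the processing grid) over reliable collagen voxels
  field_rmse <- NULL
  if (!is.null(fields) && length(fields) > 1L) {
    coll0 <- collagen[[1]]$data
    amp_floor <- stats::median(coll0[coll0 > 0])
    # evaluation region: textured collagen, away from the cell boundary and
    # from the FOV border (the field is unconstrained in zero-filled margins)
    b <- 6L
    interior <- array(FALSE, gd$shape)
    interior[(1 + b):(gd$shape[1] - b), (1 + b):(gd$shape[2] - b),
             (1 + b):(gd$shape[3] - b)] <- TRUE
    field_rmse <- vapply(2:length(fields$items), function(k) {
      est <- fields$items[[k]]
      tf <- truth$fields[[k]]
      near_cell <- gauss_blur(masks$cleaned[[k]]$data, rep(2, 3)) > 0.01
      ok <- coll0 > amp_floor & !near_cell & interior
      err2 <- ((est$ux - resample_to_grid(tf$ux, g, gd)) / gd$pitch[1])^2 +
              ((est$uy - resample_to_grid(tf$uy, g, gd)) / gd$pitch[2])^2 +
              ((est$uz - resample_to_grid(tf$uz, g, gd)) / gd$pitch[3])^2
      sqrt(mean(err2[ok]))
    }, numeric(1))
  }
  list(drift_max_err_vox = max(drift_err), drift_err_vox = drift_err,
       dice = dice, dice_min = min(dice),
       collagen_on_mask_max = max(collagen_on_mask),
       field_rmse_vox = field_rmse)
}

#' Summarise a pipeline run
#'
#' Per-time-point summary of a [run_pipeline()] manifest: cleaned-mask
#' volume, cumulative drift, mean off-mask displacement magnitude, and
#' ground-truth Dice where available. Missing stages produce a partial
#' summary with a warning.
#'
#' @param manifest a `run_manifest`.
#' @return A data.frame, one row per time-point.
#' @export
summarize_run <- function(manifest) {
  p <- manifest$products
  ts <- manifest$timestamps
  n <- length(ts)
  out <- data.frame(t_min = ts)
  if (!is.null(p$masks)) {
    out$mask_voxels <- vapply(p$masks$cleaned, function(m) sum(m$data), numeric(1))
  } else warning("masks missing from manifest; partial summary")
  if (!is.null(p$drift)) {
    cum <- t(vapply(p$drift, `[[`, numeric(2), "cumulative_shift"))
    out$cum_dx_vox <- cum[seq_len(n), 1]
    out$cum_dy_vox <- cum[seq_len(n), 2]
  }
  if (!is.null(p$fields)) {
    mags <- rep(NA_real_, n)
    for (k in seq_along(p$fields$items)) {
      f <- p$fields$items[[k]]
      idx <- match(f$timestamp, ts)
      m <- field_magnitude(f)
      if (!is.null(p$masks)) m <- m[p$masks$cleaned[[idx]]$data == 0]
      mags[idx] <- mean(m)
    }
    out$mean_disp_um <- mags
  }
  if (!is.null(manifest$report)) out$dice <- manifest$report$dice
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> speckle4d", x$version, "seed", x$seed, "\n")
  cat("stages (s):", paste(sprintf("%s=%.1f", names(x$timings), x$timings),
                           collapse = ", "), "\n")
  if (!is.null(x$report)) {
    cat(sprintf("validation: drift max err %.3f vox; Dice min %.3f; collagen-on-mask max %g\n",
                x$report$drift_max_err_vox, x$report$dice_min,
                x$report$collagen_on_mask_max))
    if (!is.null(x$report$field_rmse_vox))
      cat("field RMSE (vox):",
          paste(sprintf("%.3f", x$report$field_rmse_vox), collapse = ", "), "\n")
  }
  invisible(x)
}
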