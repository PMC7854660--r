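test_that("demons parameters validate and default to the protocol settings", {
  p <- demons_params()
  expect_equal(p$pyramid_levels, 3L)
  expect_equal(p$iterations_per_level, 100L)
  expect_equal(p$smoothing_sigma, 2)
  expect_error(demons_params(pyramid_levels = 0), "pyramid_levels")
  expect_error(demons_params(smoothing_sigma = -1), "smoothing_sigma")
})

test_that("registering a volume to itself yields a vanishing field", {
  cs <- small_speckle(seed = 2)
  f <- demons_register(cs, cs, fast_demons())
  expect_lt(max(field_magnitude(f)) / cs$grid$pitch[1], 0.05)
  expect_error(demons_register(cs, volume_image(array(1, cs$grid$shape), cs$grid)),
               "constant")
})

test_that("demons recovers a 2-voxel translation in the interior", {
  cs <- small_speckle(seed = 2, shape = c(64L, 64L, 48L))
  g <- cs$grid
  moved <- volume_image(pmax(speckle4d:::fourier_shift3(cs$data, c(2, 0, 0)), 0), g)
  f <- demons_register(moved, cs)   # fixed = shifted, moving = original
  ctr <- interior_region(g$shape, 12)
  # pull-back convention: fixed(x) = moving(x + u) with u = -2 voxels in x
  expect_lt(abs(mean(f$ux[ctr]) / g$pitch[1] + 2), 0.25)
  expect_lt(mean(abs(f$uy[ctr])) / g$pitch[2], 0.15)
  expect_lt(mean(abs(f$uz[ctr])) / g$pitch[3], 0.15)
})

test_that("demons recovers a radial contraction and its amplitude within 15%", {
  shape <- c(64L, 64L, 48L)
  cs <- small_speckle(seed = 4, shape = shape)
  g <- cs$grid
  ctr_um <- grid_center_um(g)
  r <- radius_array(g, ctr_um)
  R <- 18
  for (A_vox in c(1, 3)) {
    u <- radial_contraction_field(ctr_um, A_vox * g$pitch[1], R, 2, g)
    gf <- displacement_field(-u$ux, -u$uy, -u$uz, g)
    warped <- warp_volume(cs, gf)
    warped$data <- pmax(warped$data, 0)
    f <- demons_register(warped, cs)
    ok <- r > R & cs$data > median(cs$data) & interior_region(shape, 7)
    rmse <- sqrt(mean((((f$ux - gf$ux) / g$pitch[1])^2 +
                       ((f$uy - gf$uy) / g$pitch[2])^2 +
                       ((f$uz - gf$uz) / g$pitch[3])^2)[ok]))
    expect_lt(rmse, 0.5)
    # surface amplitude estimated by extrapolating the far-field decay law
    # |u| = A (R/r)^p back to r = R, staying one smoothing length away from
    # the surface where the regularised field flattens the kink
    far <- r > R + 4 * g$pitch[1] & r < 40 & interior_region(shape, 7)
    A_est <- median((field_magnitude(f) * (r / R)^2)[far]) / g$pitch[1]
    expect_lt(abs(A_est - A_vox) / A_vox, 0.15)
  }
})

test_that("field smoothness increases monotonically with the smoothing sigma", {
  cs <- small_speckle(seed = 6)
  g <- cs$grid
  ctr_um <- grid_center_um(g)
  u <- radial_contraction_field(ctr_um, 2 * g$pitch[1], 15, 2, g)
  gf <- displacement_field(-u$ux, -u$uy, -u$uz, g)
  warped <- warp_volume(cs, gf)
  warped$data <- pmax(warped$data, 0)
  lap_energy <- function(f) {
    lap <- function(a) {
      d <- dim(a)
      (a[c(2:d[1], d[1]), , ] + a[c(1, 1:(d[1] - 1)), , ] +
       a[, c(2:d[2], d[2]), ] + a[, c(1, 1:(d[2] - 1)), ] +
       a[, , c(2:d[3], d[3])] + a[, , c(1, 1:(d[3] - 1))] - 6 * a)
    }
    sum(lap(f$ux)^2 + lap(f$uy)^2 + lap(f$uz)^2)
  }
  en <- sapply(c(1, 2, 4), function(s)
    lap_energy(demons_register(warped, cs, demons_params(2, 30, s))))
  expect_true(all(is.finite(en)))
  expect_lt(en[2], en[1])
  expect_lt(en[3], en[2])
})

test_that("track_series follows a ramped contraction monotonically and honours the horizon", {
  spec <- small_spec(seed = 8, contraction_A_um = 3 * 1.88,
                     drift_um_per_step = c(0, 0), radius_um = 14,
                     n_protrusions = 0L)
  out <- generate_timelapse(spec, 4, n_frames = 4)
  collagen <- make_collagen_channel(
    lapply(out$series$items, mean_projection),
    lapply(out$truth$masks, function(m) m))
  fields <- track_series(collagen, fast_demons(), horizon_min = 1440)
  expect_length(fields, 4L)
  expect_true(all(field_magnitude(fields$items[[1]]) == 0))

  g <- spec$grid
  r <- radius_array(g, spec$center_um)
  far <- abs(r - 2 * 14) < 2 & interior_region(g$shape, 6)
  mags <- sapply(2:4, function(k) mean(field_magnitude(fields$items[[k]])[far]))
  expect_equal(cor(mags, 1:3, method = "spearman"), 1)

  # horizon in the middle of the series: later time-points skipped
  suppressMessages(
    short <- track_series(collagen, fast_demons(), horizon_min = 45))
  expect_length(short, 2L)

  expect_warning(none <- track_series(collagen, fast_demons(), horizon_min = 0),
                 "horizon")
  expect_length(none, 0L)

  shifted <- collagen
  shifted[[1]]$timestamp <- 10
  expect_error(track_series(shifted, fast_demons()), "t = 0")
})

test_that("noise floor is zero for identical volumes and stable under rescaling", {
  cs <- small_speckle(seed = 10)
  nf0 <- estimate_noise_floor(list(list(cs, cs)), fast_demons())
  expect_lt(nf0$floor_um / cs$grid$pitch[1], 1e-3)

  spec <- small_spec(seed = 10, contraction_A_um = 0, drift_um_per_step = c(0, 0))
  out <- generate_timelapse(spec, 2, n_frames = 4)
  m <- lapply(out$series$items, mean_projection)
  nf1 <- estimate_noise_floor(list(m), fast_demons())
  scaled <- lapply(m, function(v) volume_image(v$data * 9, v$grid))
  nf2 <- estimate_noise_floor(list(scaled), fast_demons())
  expect_lt(abs(nf2$floor_um - nf1$floor_um) / nf1$floor_um, 0.1)
  expect_error(estimate_noise_floor(list()), "pair")
})

test_that("arrow export subsamples the off-mask field in physical units", {
  g <- voxel_grid(c(10, 10, 8), pitch = c(2, 2, 2), origin = c(1, 1, 1))
  zero <- array(0, c(10, 10, 8))
  f <- displacement_field(zero + 1, zero - 2, zero, g)
  tab <- export_arrows(f, stride = 3)
  expect_equal(nrow(tab), length(seq(1, 10, 3))^2 * length(seq(1, 8, 3)))
  expect_true(all(tab$ux == 1) && all(tab$uy == -2) && all(tab$uz == 0))
  expect_equal(min(tab$x), 1); expect_equal(max(tab$x), 1 + 9 * 2 - 0 * 2)

  fz <- displacement_field(zero, zero, zero, g)
  expect_true(all(export_arrows(fz, stride = 2)[, c("ux", "uy", "uz")] == 0))

  # stride equal to the grid size leaves at most one voxel per axis
  expect_lte(nrow(export_arrows(f, stride = 10)), 8)

  mask <- volume_image(array(1, c(10, 10, 8)), g, role = "binary_mask")
  expect_equal(nrow(export_arrows(f, mask, stride = 2)), 0)
  half <- array(0, c(10, 10, 8)); half[1:5, , ] <- 1
  tabh <- export_arrows(f, volume_image(half, g, role = "binary_mask"), stride = 1)
  expect_equal(nrow(tabh), sum(half == 0))
})

test_that("jacobian_report flags folding only for folding fields", {
  g <- voxel_grid(c(12, 12, 12))
  zero <- array(0, c(12, 12, 12))
  expect_equal(jacobian_report(displacement_field(zero, zero, zero, g)), 0)
  # strong shrinking ramp: u_x = -1.5 x crosses det J < 0
  X <- outer(outer(0:11, rep(1, 12)), rep(1, 12))
  fold <- displacement_field(-1.5 * X, zero, zero, g)
  expect_gt(jacobian_report(fold), 0.5)
})
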