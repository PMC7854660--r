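test_that("mean and std projections match per-voxel brute-force statistics", {
  b <- random_burst(N = 8)
  mp <- mean_projection(b)
  sp <- std_projection(b)
  stack <- simplify2array(b$volumes)             # x, y, z, i
  mref <- apply(stack, 1:3, mean)
  sref <- apply(stack, 1:3, sd)
  expect_lt(max(abs(mp$data - mref)), 1e-12)
  expect_lt(max(abs(sp$data - sref)), 1e-12)
  expect_equal(mp$role, "mean_projection")
  expect_equal(sp$role, "std_projection")
})

test_that("projections honour their closed forms and degenerate cases", {
  g <- voxel_grid(c(3, 3, 3))
  a <- array(1, c(3, 3, 3)); b <- array(3, c(3, 3, 3))
  burst <- burst_stack(list(a, b), g)
  expect_true(all(mean_projection(burst)$data == 2))
  expect_true(all(abs(std_projection(burst)$data - 2 / sqrt(2)) < 1e-14))
  same <- burst_stack(list(a, a, a), g)
  expect_true(all(std_projection(same)$data == 0))
  expect_error(std_projection(burst_stack(list(a), g)), "N >= 2")
})

test_that("projections are permutation-invariant and scale-covariant", {
  b <- random_burst(N = 5, seed = 13)
  perm <- burst_stack(b$volumes[c(3, 1, 5, 2, 4)], b$grid)
  expect_lt(max(abs(mean_projection(b)$data - mean_projection(perm)$data)), 1e-12)
  expect_lt(max(abs(std_projection(b)$data - std_projection(perm)$data)), 1e-12)
  scaled <- burst_stack(lapply(b$volumes, `*`, 3.5), b$grid)
  expect_equal(mean_projection(scaled)$data, 3.5 * mean_projection(b)$data,
               tolerance = 1e-12)
  expect_equal(std_projection(scaled)$data, 3.5 * std_projection(b)$data,
               tolerance = 1e-12)
})

test_that("the std projection separates decorrelating from static speckle", {
  cs <- small_speckle(seed = 5)
  mask <- make_spheroid_mask(small_spec(seed = 5))
  b <- simulate_burst(cs, mask, rho = 0.5, N = 8, seed = 21)
  sp <- std_projection(b)
  inside <- mask$data == 1
  # driver of segmentation: >= 5x contrast between cell and collagen regions
  expect_gt(mean(sp$data[inside]) / max(mean(sp$data[!inside]), 1e-300), 5)
})

test_that("isotropic down-sampling reproduces the published voxel pitches", {
  # monoculture: 0.75 mm over 768 px, 768:400 -> 1.875 um (prints as 1.88)
  g1 <- voxel_grid(c(16, 16, 16), pitch = c(750 / 768, 750 / 768, 1))
  v1 <- volume_image(array(1, c(16, 16, 16)), g1)
  d1 <- downsample_isotropic(v1)
  expect_equal(d1$grid$pitch, rep(1.875, 3), tolerance = 1e-12)
  expect_equal(signif(d1$grid$pitch[1], 3), 1.88)

  # co-culture: 937.5 um over 768 px -> 2.34375 um (prints as 2.34)
  g2 <- voxel_grid(c(16, 16, 16), pitch = c(937.5 / 768, 937.5 / 768, 1))
  d2 <- downsample_isotropic(volume_image(array(2, c(16, 16, 16)), g2))
  expect_equal(signif(d2$grid$pitch[1], 3), 2.34)

  # constant volumes stay constant
  expect_lt(max(abs(d1$data - 1)), 1e-12)
  expect_lt(max(abs(d2$data - 2)), 1e-12)

  # physical extent is approximately conserved
  expect_lt(max(abs(grid_extent(d1$grid) - grid_extent(g1))),
            max(d1$grid$pitch))

  expect_error(downsample_isotropic(v1, ratio = c(400, 768)), "ratio")
})

test_that("down-sampling a band-limited volume conserves its mean within 1%", {
  g <- voxel_grid(c(32, 32, 24), pitch = c(1, 1, 1.5))
  sp <- make_collagen_speckle(small_spec(seed = 17, shape = c(32L, 32L, 24L),
                                         radius_um = 10))
  a <- speckle4d:::gauss_blur(sp$data, c(2, 2, 2)) + 1
  v <- volume_image(a, g)
  d <- downsample_isotropic(v)
  expect_lt(abs(mean(d$data) - mean(a)) / mean(a), 0.01)
})

test_that("depth background is recovered exactly from the periphery median", {
  g <- voxel_grid(c(20, 20, 10))
  B <- seq(2, 0.5, length.out = 10)
  vol <- volume_image(array(rep(B, each = 400), c(20, 20, 10)), g)
  prof <- estimate_depth_background(vol, margin = 0.15)
  expect_equal(prof$values, B, tolerance = 1e-15)

  # a bright central blob does not bias the peripheral median
  contaminated <- vol
  contaminated$data[8:13, 8:13, ] <- 100
  prof2 <- estimate_depth_background(contaminated, margin = 0.15)
  expect_lt(max(abs(prof2$values - B)), 1e-12)

  zero <- volume_image(array(0, c(20, 20, 10)), g)
  expect_true(all(estimate_depth_background(zero)$values == 0))

  expect_error(estimate_depth_background(vol, margin = 0.5), "margin")
})

test_that("background subtraction is a clamped per-depth shift", {
  g <- voxel_grid(c(20, 20, 10))
  B <- seq(2, 0.5, length.out = 10)
  vol <- volume_image(array(rep(B, each = 400), c(20, 20, 10)), g)
  prof <- estimate_depth_background(vol)
  out <- subtract_background(vol, prof)
  expect_true(all(out$data == 0))
  expect_equal(out$role, "cell_channel")

  zero_prof <- prof; zero_prof$values <- rep(0, 10)
  expect_identical(subtract_background(vol, zero_prof)$data, vol$data)

  big <- prof; big$values <- rep(10, 10)
  expect_true(all(subtract_background(vol, big)$data == 0))   # clamped

  short <- prof; short$values <- 1:3
  expect_error(subtract_background(vol, short), "length")
})

test_that("background removal on the phantom leaves a small peripheral residual", {
  spec <- small_spec(seed = 19)
  out <- generate_timelapse(spec, 1, n_frames = 4)
  sp <- std_projection(out$series$items[[1]])
  prof <- estimate_depth_background(sp, margin = 0.15)
  cell <- subtract_background(sp, prof)
  resid <- estimate_depth_background(cell, margin = 0.15)
  expect_lt(max(resid$values), spec$noise_sd)
})

test_that("depth-coded projection equals the brute-force per-channel MIP", {
  g <- voxel_grid(c(7, 6, 5))
  set.seed(23)
  vol <- volume_image(array(runif(210), c(7, 6, 5)), g)
  pal <- function(n) grDevices::hcl.colors(n, "Spectral")
  img <- depth_coded_projection(vol, reference_z = 2, palette = pal)
  cols <- t(grDevices::col2rgb(pal(5))) / 255
  v <- vol$data / max(vol$data)
  for (ch in 1:3) {
    ref <- apply(sweep(v, 3, cols[, ch], `*`), 1:2, max)
    expect_equal(img[, , ch], ref, tolerance = 1e-14)
  }

  # single bright voxel: its pixel carries exactly the colour of its depth
  one <- array(0, c(7, 6, 5)); one[3, 4, 2] <- 1
  img1 <- depth_coded_projection(volume_image(one, g), reference_z = 2,
                                 palette = pal)
  expect_equal(img1[3, 4, ], unname(cols[2, ]), tolerance = 1e-14)
  expect_true(all(img1[-3, , ] == 0))
})

test_that("enface_slice extracts the requested lateral plane", {
  g <- voxel_grid(c(4, 5, 6))
  set.seed(3)
  vol <- volume_image(array(rnorm(120)^2, c(4, 5, 6)), g)
  expect_identical(enface_slice(vol, 0), vol$data[, , 1])
  expect_identical(enface_slice(vol, 5), vol$data[, , 6])
  expect_error(enface_slice(vol, 6), "range")
  flat <- volume_image(array(2, c(4, 5, 6)), g)
  expect_true(all(enface_slice(flat, 3) == 2))
})
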