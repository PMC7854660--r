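test_that("collagen speckle is deterministic, Rayleigh-distributed, fully developed", {
  spec <- small_spec(seed = 3, shape = c(64L, 64L, 48L), radius_um = 25)
  a <- make_collagen_speckle(spec)
  b <- make_collagen_speckle(spec)
  expect_identical(a$data, b$data)

  # fully developed speckle: contrast = sqrt(4/pi - 1) ~ 0.5227
  contrast <- sd(a$data) / mean(a$data)
  expect_lt(abs(contrast - sqrt(4 / pi - 1)), 0.02)

  # amplitude ~ Rayleigh(sigma); sigma from the second moment: E[A^2] = 2 sigma^2.
  # Sample on a coarse stride so the PSF-induced spatial correlation does not
  # bias the KS statistic.
  sig <- sqrt(mean(a$data^2) / 2)
  samp <- a$data[seq(1, length(a$data), by = 17)][1:1e4]
  ks <- suppressWarnings(
    ks.test(samp, function(q) 1 - exp(-q^2 / (2 * sig^2))))
  expect_gt(ks$p.value, 0.01)

  # zero density -> zero volume
  expect_true(all(make_collagen_speckle(small_spec(density = 0))$data == 0))
})

test_that("spheroid mask matches the analytic sphere volume and grows monotonically", {
  spec0 <- phantom_spec(grid = small_grid(c(64L, 64L, 48L)), radius_um = 30,
                        n_protrusions = 0L, seed = 1)
  m <- make_spheroid_mask(spec0)
  analytic <- 4 / 3 * pi * 30^3 / prod(spec0$grid$pitch)
  expect_lt(abs(sum(m$data) - analytic) / analytic, 0.02)

  grow <- small_spec(growth_um_per_step = 1)
  m1 <- make_spheroid_mask(grow, step = 1)
  m2 <- make_spheroid_mask(grow, step = 3)
  expect_true(all(m2$data >= m1$data))

  spec_empty <- small_spec()
  spec_empty$radius_um <- 0          # degenerate geometry, bypassing validation
  expect_true(all(make_spheroid_mask(spec_empty)$data == 0))
})

test_that("burst simulation decorrelates cell speckle at the requested rate", {
  spec <- small_spec(seed = 5, shape = c(64L, 64L, 48L), radius_um = 25)
  cs <- make_collagen_speckle(spec)
  mask <- make_spheroid_mask(spec)
  inside <- mask$data == 1
  expect_gt(sum(inside), 1e4)

  b1 <- simulate_burst(cs, mask, rho = 1, N = 3, seed = 6)
  expect_identical(b1$volumes[[1]], b1$volumes[[3]])
  expect_true(all(std_projection(b1)$data == 0))

  b0 <- simulate_burst(cs, mask, rho = 0, N = 4, seed = 6)
  cors <- sapply(1:3, function(i)
    cor(b0$volumes[[i]][inside], b0$volumes[[i + 1]][inside]))
  expect_lt(mean(abs(cors)), 0.1)

  # outside the mask every frame equals the static volume: std exactly 0
  sp <- std_projection(b0)
  expect_identical(max(sp$data[!inside]), 0)

  expect_error(simulate_burst(cs, mask, rho = 0.2, N = 1, seed = 1), "N")
})

test_that("radial contraction field follows the analytic profile", {
  g <- small_grid()
  ctr <- grid_center_um(g)
  expect_true(all(field_magnitude(
    radial_contraction_field(ctr, 0, 20, 2, g)) == 0))

  f <- radial_contraction_field(ctr, A = 3, R = 20, p = 2, grid = g)
  r <- radius_array(g, ctr)
  m <- field_magnitude(f)
  at_R <- abs(r - 20) < 0.5
  expect_lt(max(abs(m[at_R] - 3)), 3 * 0.06)      # |u|(R) = A
  at_2R <- abs(r - 40) < 0.3
  expect_lt(max(abs(m[at_2R] - 3 / 4)), 0.06)     # |u|(2R) = A/4 at p = 2
  # field points toward the center: u . (x - c) < 0 off-center
  cx <- (ctr - g$origin) / g$pitch
  X <- ((0:(g$shape[1] - 1)) - cx[1]) * g$pitch[1]
  ip <- f$ux * outer(outer(X, rep(1, g$shape[2])), rep(1, g$shape[3]))
  expect_lt(max(ip[abs(r - 20) < 2]), 1e-12)

  expect_error(radial_contraction_field(g$origin - 100, 1, 20, 2, g), "outside")
})

test_that("warp_volume is exact on the identity and on integer translations", {
  cs <- small_speckle(seed = 4)
  g <- cs$grid
  zero <- array(0, g$shape)
  id <- warp_volume(cs, displacement_field(zero, zero, zero, g))
  expect_lt(max(abs(id$data - cs$data)), 1e-12)

  # uniform +2 voxel x displacement: out(x) = in(x + 2)
  two <- array(2 * g$pitch[1], g$shape)
  tr <- warp_volume(cs, displacement_field(two, zero, zero, g))
  nx <- g$shape[1]
  expect_equal(tr$data[1:(nx - 2), , ], cs$data[3:nx, , ], tolerance = 1e-12)
  expect_true(all(attr(tr, "inside")[(nx - 1):nx, , ] == 0))
  expect_true(all(tr$data[(nx - 1):nx, , ] == 0))
})

test_that("warping by u then -u restores a smooth volume within tolerance", {
  g <- small_grid()
  # band-limited phantom: heavily blurred speckle
  a <- speckle4d:::gauss_blur(small_speckle(seed = 9)$data, c(3, 3, 3))
  v <- volume_image(a, g)
  ctr <- grid_center_um(g)
  f <- radial_contraction_field(ctr, A = 2, R = 15, p = 2, grid = g)
  fwd <- warp_volume(v, f)
  fb <- displacement_field(-f$ux, -f$uy, -f$uz, g)
  back <- warp_volume(fwd, fb)
  rng <- diff(range(a))
  core <- interior_region(g$shape, 6)
  expect_lt(max(abs(back$data - a)[core]), 0.05 * rng)
})

test_that("generate_timelapse produces consistent ground truth", {
  spec <- small_spec(seed = 10, drift_um_per_step = c(2, 0) * 1.88,
                     contraction_A_um = 3)
  out <- generate_timelapse(spec, 3, n_frames = 4)
  expect_length(out$series, 3L)

  # cumulative drift is k * delta
  expect_equal(out$truth$drift_um,
               outer(0:2, spec$drift_um_per_step), tolerance = 1e-12)

  # determinism: bit-identical rerun
  out2 <- generate_timelapse(spec, 3, n_frames = 4)
  expect_identical(out$series$items[[3]]$volumes, out2$series$items[[3]]$volumes)

  # single time-point: zero truth
  one <- generate_timelapse(small_spec(seed = 10), 1, n_frames = 2)
  expect_true(all(field_magnitude(one$truth$fields[[1]]) == 0))
  expect_true(all(one$truth$drift_um == 0))

  # ground-truth consistency: warping t0 collagen by the stored field
  # reproduces the noiseless collagen of time t (away from borders)
  w <- warp_volume(out$truth$collagen0, out$truth$fields[[3]])
  core <- interior_region(spec$grid$shape, 5)
  err <- abs(pmax(w$data, 0) - out$truth$collagen[[3]]$data)
  expect_lt(max(err[core]), 1e-9)

  # off-grid drift guard
  far <- small_spec(seed = 1, drift_um_per_step = c(30, 0))
  expect_error(generate_timelapse(far, 10), "off-grid")
})

test_that("with no contraction and no drift, off-mask voxels are static across the series", {
  spec <- small_spec(seed = 12, contraction_A_um = 0,
                     drift_um_per_step = c(0, 0), noise_sd = 0,
                     background_peak = 0)
  out <- generate_timelapse(spec, 3, n_frames = 3)
  outside <- out$truth$masks[[1]]$data == 0
  ref <- out$series$items[[1]]$volumes[[1]]
  for (k in 1:3)
    for (f in out$series$items[[k]]$volumes)
      expect_identical(f[outside], ref[outside])
})
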