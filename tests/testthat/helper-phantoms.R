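# shared fixtures: small desk-scale phantoms built in code

small_grid <- function(shape = c(48L, 48L, 32L), pitch = 1.88) {
  voxel_grid(shape, pitch = pitch)
}

small_spec <- function(seed = 2, shape = c(48L, 48L, 32L), radius_um = 20, ...) {
  phantom_spec(grid = small_grid(shape), radius_um = radius_um,
               protrusion_length_um = 10, protrusion_width_um = 6,
               seed = seed, ...)
}

small_speckle <- function(seed = 2, shape = c(48L, 48L, 32L)) {
  make_collagen_speckle(small_spec(seed = seed, shape = shape))
}

random_burst <- function(N = 8, shape = c(6L, 5L, 4L), seed = 99) {
  set.seed(seed)
  g <- voxel_grid(shape, pitch = 1)
  vols <- lapply(seq_len(N), function(i) array(abs(rnorm(prod(shape))), shape))
  burst_stack(vols, g)
}

# quick demons settings for property tests that do not need the full budget
fast_demons <- function(levels = 2L, iters = 30L, sigma = 2)
  demons_params(levels, iters, sigma)

grid_center_um <- function(g) g$origin + (g$shape - 1) * g$pitch / 2

# radial distance array (um) from a center
radius_array <- function(g, center_um) {
  cx <- (center_um - g$origin) / g$pitch
  X <- ((0:(g$shape[1] - 1)) - cx[1]) * g$pitch[1]
  Y <- ((0:(g$shape[2] - 1)) - cx[2]) * g$pitch[2]
  Z <- ((0:(g$shape[3] - 1)) - cx[3]) * g$pitch[3]
  sqrt(outer(outer(X^2, Y^2, `+`), Z^2, `+`))
}

# interior logical array excluding a border of b voxels
interior_region <- function(shape, b) {
  a <- array(FALSE, shape)
  a[(1 + b):(shape[1] - b), (1 + b):(shape[2] - b), (1 + b):(shape[3] - b)] <- TRUE
  a
}
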