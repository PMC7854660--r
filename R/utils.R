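# internal numeric helpers

# signed FFT frequency indices for length n (cycles per array, integer bins)
fft_freq_idx <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Sub-pixel circular translation by spectral phase ramp: content moves by
# +shift voxels, i.e. out(x) = vol(x - shift). Exact for band-limited data.
fourier_shift3 <- function(vol, shift) {
  d <- dim(vol)
  if (all(shift == 0)) return(vol)
  kx <- fft_freq_idx(d[1]) / d[1]
  ky <- fft_freq_idx(d[2]) / d[2]
  kz <- fft_freq_idx(d[3]) / d[3]
  # apply the separable phase ramp axis by axis (avoids a full 3D ramp array)
  F <- stats::fft(vol)
  F <- F * as.vector(exp(-2i * pi * kx * shift[1]))
  F <- sweep(F, 2, exp(-2i * pi * ky * shift[2]), `*`)
  F <- sweep(F, 3, exp(-2i * pi * kz * shift[3]), `*`)
  Re(stats::fft(F, inverse = TRUE)) / length(vol)
}

# zero the circularly wrapped border after a translation by `shift`
zero_wrapped_border <- function(vol, shift) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- shift[ax]
    if (s == 0) next
    w <- min(d[ax], ceiling(abs(s)))
    idx <- if (s > 0) seq_len(w) else (d[ax] - w + 1):d[ax]
    if (ax == 1) vol[idx, , ] <- 0
    if (ax == 2) vol[, idx, ] <- 0
    if (ax == 3) vol[, , idx] <- 0
  }
  vol
}

# Gaussian blur of a 3D array, sigma per axis in voxels
gauss_blur <- function(vol, sigma, wrap = FALSE) {
  if (all(sigma <= 0)) return(vol)
  cpp_gauss_blur3(vol, dim(vol), as.numeric(sigma), wrap)
}

# Dice coefficient between two binary arrays
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}
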