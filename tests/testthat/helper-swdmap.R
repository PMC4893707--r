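# shared helpers: small constructors and measurement utilities

# tf_map on the rescaled common axis filled with given values
make_rescaled_map <- function(values, kind = "power") {
  n_bins <- nrow(values)
  grid <- tf_grid(0, 1)
  grid$times <- seq(-0.1, 1.1, length.out = n_bins)
  m <- tf_map(matrix(1, n_bins, length(grid$freqs)), grid, kind)
  m$values <- values
  m$meta$rescaled <- TRUE
  m
}

# tiny normalized map with pooling metadata, for rft pooling tests
make_pooled_map <- function(values, animal, condition) {
  m <- make_rescaled_map(values, "power")
  m$kind <- "z-power"
  m$meta$animal <- animal
  m$meta$condition <- condition
  m
}

# FWHM of a sampled unimodal profile, with linear interpolation of the
# half-maximum crossings
measure_fwhm <- function(v, axis) {
  h <- max(v) / 2
  above <- which(v >= h)
  i1 <- above[1]; i2 <- above[length(above)]
  left <- if (i1 == 1) axis[1] else {
    axis[i1 - 1] + (h - v[i1 - 1]) / (v[i1] - v[i1 - 1]) *
      (axis[i1] - axis[i1 - 1])
  }
  right <- if (i2 == length(v)) axis[length(v)] else {
    axis[i2] + (v[i2] - h) / (v[i2] - v[i2 + 1]) *
      (axis[i2 + 1] - axis[i2])
  }
  right - left
}

# in-band power from the raw periodogram (independent of the Welch path)
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  psd <- Mod(X)^2 / (fs * n)
  sel <- f >= band[1] & f <= band[2]
  2 * mean(psd[sel]) * diff(band)
}
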