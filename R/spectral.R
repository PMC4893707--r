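#' Sliding-window Welch spectral estimation
#'
#' Time-frequency power and magnitude-squared coherence on a fixed analysis
#' grid: 4 to 20 Hz in 0.1 Hz steps, a 4 s window positioned every 100 ms.
#' Within each window the Welch estimate averages Hann-tapered, constant-
#' detrended 1 s sub-segments with 50% overlap (7 sub-segments). The 0.1 Hz
#' grid is finer than the native resolution of a 1 s sub-segment; the DFT is
#' evaluated directly at the grid frequencies, which is exactly equivalent to
#' zero-padding to fs/0.1 samples -- spectral interpolation, not added
#' resolution.
#'
#' @name spectral
NULL

#' Time-frequency analysis grid
#'
#' @param t0,t1 first and last window centre, seconds (relative to trace
#'   start).
#' @param freqs frequency axis, Hz; default 4-20 Hz in 0.1 Hz steps
#'   (161 bins).
#' @param dt window-centre step, seconds.
#' @param window_s window length, seconds.
#' @param sub_s,overlap Welch sub-segment length (s) and fractional overlap.
#' @return object of class `tf_grid` with `times`, `freqs` and window
#'   parameters.
#' @export
tf_grid <- function(t0, t1, freqs = seq(4, 20, by = 0.1), dt = 0.1,
                    window_s = 4, sub_s = 1, overlap = 0.5) {
  if (t1 < t0) stop("t1 must be >= t0", call. = FALSE)
  if (any(freqs < 0)) stop("frequencies must be >= 0", call. = FALSE)
  times <- seq(t0, t1, by = dt)
  structure(list(times = times, freqs = freqs, dt = dt, window_s = window_s,
                 sub_s = sub_s, overlap = overlap),
            class = "tf_grid")
}

#' Time-frequency map container
#'
#' @param values numeric matrix, time x frequency.
#' @param grid the [tf_grid()] the map lives on.
#' @param kind one of `"power"`, `"coherence"`, `"z-power"`, `"z-coherence"`.
#' @param channel channel label or pair id.
#' @param event_id event identifier.
#' @param meta list of estimator metadata (number of averaged sub-segments,
#'   window parameters, fs, normalization state).
#' @return object of class `tf_map`.
#' @export
tf_map <- function(values, grid, kind, channel = NA, event_id = NA,
                   meta = list()) {
  kind <- match.arg(kind, c("power", "coherence", "z-power", "z-coherence"))
  if (!is.matrix(values) ||
      nrow(values) != length(grid$times) ||
      ncol(values) != length(grid$freqs))
    stop("values must be a time x frequency matrix matching the grid",
         call. = FALSE)
  if (kind == "power" && any(values < 0))
    stop("power must be non-negative", call. = FALSE)
  if (kind == "coherence" && (any(values < 0) || any(values > 1 + 1e-9)))
    stop("coherence must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, times = grid$times, freqs = grid$freqs,
                 kind = kind, channel = channel, event_id = event_id,
                 meta = meta),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("tf_map [%s] %d times x %d freqs", x$kind,
              length(x$times), length(x$freqs)))
  if (!is.na(x$channel)) cat(", channel", x$channel)
  cat("\n")
  invisible(x)
}

#' @export
plot.tf_map <- function(x, ...) {
  graphics::image(x$times, x$freqs, x$values,
                  xlab = if (isTRUE(x$meta$rescaled)) "seizure time (0-1)"
                         else "time (s)",
                  ylab = "frequency (Hz)",
                  main = x$kind, ...)
  invisible(x)
}

## Welch auto/cross spectra for all window centres at once.
## Returns n_t x n_f matrices Pxx (and Pyy, plus complex Pxy if y given),
## already averaged over the K sub-segments.
welch_sliding <- function(x, y = NULL, fs, grid) {
  n <- length(x)
  if (!is.null(y) && length(y) != n)
    stop("traces must have equal length", call. = FALSE)
  win_len <- round(grid$window_s * fs)
  if (n < win_len)
    stop("trace shorter than one analysis window", call. = FALSE)
  seg_len <- round(grid$sub_s * fs)
  hop <- round(seg_len * (1 - grid$overlap))
  n_seg <- floor((win_len - seg_len) / hop) + 1L
  s0 <- round((grid$times - grid$window_s / 2) * fs)
  if (any(s0 < 0) || any(s0 + win_len > n))
    stop("trace does not cover every analysis window", call. = FALSE)
  n_t <- length(grid$times)
  ## segment start indices, time-major (each window's K segments contiguous)
  starts <- as.vector(t(outer(s0, (seq_len(n_seg) - 1L) * hop, "+")))
  idx <- outer(seq_len(seg_len), starts, "+")
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1)))
  scale <- 2 / (fs * sum(w^2))
  tt <- (seq_len(seg_len) - 1) / fs
  C <- cos(2 * pi * outer(tt, grid$freqs))
  S <- sin(2 * pi * outer(tt, grid$freqs))

  dft <- function(z) {
    segs <- matrix(z[idx], nrow = seg_len)
    segs <- segs - rep(colMeans(segs), each = seg_len)   # constant detrend
    segs <- segs * w
    list(re = crossprod(C, segs), im = -crossprod(S, segs))
  }
  avg_over_segs <- function(m) {
    ## m is n_f x (n_t * n_seg), time-major
    a <- array(m, dim = c(length(grid$freqs), n_seg, n_t))
    t(colMeans(aperm(a, c(2, 1, 3))))
  }
  X <- dft(x)
  Pxx <- avg_over_segs((X$re^2 + X$im^2) * scale)
  out <- list(Pxx = Pxx, K = n_seg)
  if (!is.null(y)) {
    Y <- dft(y)
    out$Pyy <- avg_over_segs((Y$re^2 + Y$im^2) * scale)
    out$Pxy_re <- avg_over_segs((X$re * Y$re + X$im * Y$im) * scale)
    out$Pxy_im <- avg_over_segs((X$im * Y$re - X$re * Y$im) * scale)
  }
  out
}

#' Sliding Welch power map
#'
#' @param trace numeric vector (microvolts); must cover `[t - window_s/2,
#'   t + window_s/2]` for every grid time.
#' @param fs sampling rate, Hz.
#' @param grid a [tf_grid()].
#' @param channel,event_id metadata carried into the map.
#' @return [tf_map()] of kind `"power"`, units uV^2/Hz.
#' @export
sliding_welch_power <- function(trace, fs, grid, channel = NA,
                                event_id = NA) {
  est <- welch_sliding(trace, NULL, fs, grid)
  tf_map(est$Pxx, grid, "power", channel, event_id,
         meta = list(K = est$K, window_s = grid$window_s, sub_s = grid$sub_s,
                     overlap = grid$overlap, fs = fs))
}

#' Sliding Welch magnitude-squared coherence map
#'
#' `|<Sxy>|^2 / (<Sxx> <Syy>)` with averages over the K sub-segments of each
#' window. With K averages, independent noises give a small-sample bias of
#' roughly 1/K rather than 0.
#'
#' @inheritParams sliding_welch_power
#' @param traceA,traceB equal-length traces.
#' @return [tf_map()] of kind `"coherence"`, values in [0, 1].
#' @export
sliding_welch_coherence <- function(traceA, traceB, fs, grid, channel = NA,
                                    event_id = NA) {
  est <- welch_sliding(traceA, traceB, fs, grid)
  msc <- (est$Pxy_re^2 + est$Pxy_im^2) / (est$Pxx * est$Pyy)
  msc[!is.finite(msc)] <- 0
  msc <- pmin(pmax(msc, 0), 1)
  tf_map(msc, grid, "coherence", channel, event_id,
         meta = list(K = est$K, window_s = grid$window_s, sub_s = grid$sub_s,
                     overlap = grid$overlap, fs = fs))
}

#' Conventional rodent LFP frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30, low gamma 30-55, high gamma
#' 65-120, epsilon 120-600 Hz; the 55-65 Hz notch region is skipped.
#'
#' @return named list of `c(lo, hi)` pairs (Hz).
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
       low_gamma = c(30, 55), high_gamma = c(65, 120),
       epsilon = c(120, 600))
}

#' Mean FFT amplitude per frequency band of an interictal segment
#'
#' The one-sided FFT amplitude spectrum of the (demeaned) segment is averaged
#' within each named band. Valid interictal segments are 2 to 10 s long
#' (epochs taken before SWD onsets). Bands lying entirely above Nyquist are
#' dropped with a warning.
#'
#' @param segment numeric vector.
#' @param fs sampling rate, Hz.
#' @param band_defs named list of `c(lo, hi)` band edges, Hz.
#' @return named numeric vector of mean band amplitudes.
#' @export
interictal_band_fft <- function(segment, fs, band_defs = default_bands()) {
  len_s <- length(segment) / fs
  if (len_s < 2 || len_s > 10)
    stop("interictal segments must be 2-10 s long (got ",
         round(len_s, 2), " s)", call. = FALSE)
  n <- length(segment)
  amp <- 2 * Mod(stats::fft(segment - mean(segment))) / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  amp <- amp[half]; f <- f[half]
  out <- numeric(0)
  for (b in names(band_defs)) {
    edges <- band_defs[[b]]
    if (edges[1] >= fs / 2) {
      warning("band ", b, " lies above Nyquist; dropped", call. = FALSE)
      next
    }
    sel <- f >= edges[1] & f < min(edges[2], fs / 2)
    out[b] <- mean(amp[sel])
  }
  out
}
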