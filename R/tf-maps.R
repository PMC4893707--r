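#' Baseline normalization, seizure-time rescaling and map smoothing
#'
#' Event maps are z-scored per frequency against the pre-event baseline (the
#' 10% pre-onset margin), their time axis is linearly rescaled to a common
#' seizure axis (onset = 0, offset = 1, margins to -0.1 and 1.1), and maps
#' are smoothed with a separable Gaussian kernel before random-field
#' inference.
#'
#' @name tf-maps
NULL

#' Per-frequency baseline z-scoring of a map
#'
#' For each frequency, the mean of the map during the baseline interval is
#' subtracted from the whole map and the result divided by the baseline
#' standard deviation (sample SD) at that frequency.
#'
#' @param map a [tf_map()] of kind power or coherence.
#' @param baseline_interval `c(t0, onset)`: time bins with
#'   `t0 <= t < onset` form the baseline; at least 2 bins required.
#' @return [tf_map()] of kind `"z-power"` or `"z-coherence"`; metadata
#'   records the baseline bins.
#' @export
normalize_map <- function(map, baseline_interval) {
  stopifnot(inherits(map, "tf_map"))
  if (map$kind %in% c("z-power", "z-coherence"))
    stop("map is already normalized", call. = FALSE)
  bl <- which(map$times >= baseline_interval[1] &
              map$times < baseline_interval[2])
  if (length(bl) < 2)
    stop("baseline interval must contain at least 2 time bins",
         call. = FALSE)
  m <- colMeans(map$values[bl, , drop = FALSE])
  s <- apply(map$values[bl, , drop = FALSE], 2, stats::sd)
  if (any(s == 0))
    stop("degenerate baseline (SD = 0) at frequency ",
         map$freqs[which(s == 0)[1]], " Hz", call. = FALSE)
  z <- sweep(sweep(map$values, 2, m, "-"), 2, s, "/")
  out <- map
  out$values <- z
  out$kind <- paste0("z-", map$kind)
  out$meta$baseline_bins <- bl
  out$meta$baseline_interval <- baseline_interval
  out
}

#' Rescale a map's time axis to the common seizure axis
#'
#' Each frequency row is linearly interpolated onto `n_bins` points spanning
#' [-0.1, 1.1] in units of seizure duration, with onset mapped to 0 and
#' offset to 1, so maps from seizures of different lengths share one axis.
#'
#' @param map a [tf_map()] whose times (seconds) cover the event window
#'   `[onset - 0.1 d, offset + 0.1 d]`.
#' @param onset,offset event boundaries, seconds.
#' @param n_bins number of points on the common axis (default 121, i.e.
#'   0.01 of the seizure duration per bin).
#' @return [tf_map()] with `times` on the unit seizure axis and
#'   `meta$rescaled = TRUE`.
#' @export
rescale_time <- function(map, onset, offset, n_bins = 121) {
  stopifnot(inherits(map, "tf_map"))
  if (offset <= onset) stop("offset must exceed onset", call. = FALSE)
  d <- offset - onset
  u <- (map$times - onset) / d
  target <- seq(-0.1, 1.1, length.out = n_bins)
  tol <- 1e-9
  if (min(u) > -0.1 + tol || max(u) < 1.1 - tol)
    stop("map does not cover the analysis window [-0.1, 1.1] of the event",
         call. = FALSE)
  vals <- apply(map$values, 2, function(col)
    stats::approx(u, col, xout = target, rule = 2)$y)
  out <- map
  out$values <- vals
  out$times <- target
  out$meta$rescaled <- TRUE
  out$meta$onset_s <- onset
  out$meta$offset_s <- offset
  out
}

## Dense smoothing matrix for one axis: Gaussian kernel with the given SD in
## bin units, truncated at +/- 4 SD, each row renormalized to unit mass so
## edges are handled by mass-preserving truncation rather than padding.
gaussian_smoother <- function(n, sd_bins, truncate = 4) {
  if (sd_bins <= 0) return(diag(n))
  half <- ceiling(truncate * sd_bins)
  i <- seq_len(n)
  W <- matrix(0, n, n)
  for (r in i) {
    j <- max(1, r - half):min(n, r + half)
    k <- exp(-((j - r)^2) / (2 * sd_bins^2))
    W[r, j] <- k / sum(k)
  }
  W
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Smooth a rescaled map with a separable Gaussian kernel
#'
#' Full widths at half maximum: `fwhm_time_fraction` of the seizure duration
#' along the rescaled time axis (default 5%) and `fwhm_freq_hz` along
#' frequency (default 5 Hz). The kernel is truncated at 4 SD and renormalized
#' at the edges (mass-preserving truncation).
#'
#' @param map a rescaled [tf_map()] (see [rescale_time()]).
#' @param fwhm_time_fraction FWHM on the unit seizure axis (> 0).
#' @param fwhm_freq_hz FWHM along frequency, Hz (> 0).
#' @return smoothed [tf_map()]; metadata records the FWHMs in bin units
#'   (`fwhm_bins_t`, `fwhm_bins_f`), used later for resel counts.
#' @export
smooth_map <- function(map, fwhm_time_fraction = 0.05, fwhm_freq_hz = 5) {
  stopifnot(inherits(map, "tf_map"))
  if (fwhm_time_fraction <= 0 || fwhm_freq_hz <= 0)
    stop("FWHM must be > 0", call. = FALSE)
  if (!isTRUE(map$meta$rescaled))
    stop("smooth_map expects a rescaled map (time FWHM is a fraction of ",
         "seizure duration)", call. = FALSE)
  dt <- map$times[2] - map$times[1]
  df <- map$freqs[2] - map$freqs[1]
  fwhm_t <- fwhm_time_fraction / dt
  fwhm_f <- fwhm_freq_hz / df
  Wt <- gaussian_smoother(length(map$times), fwhm_to_sd(fwhm_t))
  Wf <- gaussian_smoother(length(map$freqs), fwhm_to_sd(fwhm_f))
  out <- map
  out$values <- Wt %*% map$values %*% t(Wf)
  out$meta$fwhm_bins_t <- fwhm_t
  out$meta$fwhm_bins_f <- fwhm_f
  out
}
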