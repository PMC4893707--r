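#' Synthetic GAERS-like LFP sessions
#'
#' Generator for multi-channel local field potential sessions that emulate
#' recordings from a rat model of absence epilepsy: a 1/f background shared
#' across electrodes, plus recurring harmonic-rich ~7 Hz spike-wave discharge
#' (SWD) bursts inserted on all channels, with ground-truth event times and an
#' optional unilateral "treatment" effect that scales in-band SWD power and
#' reduces inter-channel coherence.
#'
#' @name synth-lfp
NULL

#' Default bilateral 2 x 5 electrode layout
#'
#' Two symmetric anteroposterior rows of five electrodes, one per hemisphere.
#' AP coordinates are chosen so that the four transection planes at +2, 0,
#' -2 and -4 mm fall midway between adjacent electrodes.
#'
#' @return data.frame with columns `label`, `hemisphere`, `ap_mm`, `ml_mm`.
#' @export
default_layout <- function() {
  ap <- c(3, 1, -1, -3, -5)
  data.frame(
    label = c(paste0("L", 1:5), paste0("R", 1:5)),
    hemisphere = rep(c("left", "right"), each = 5),
    ap_mm = rep(ap, 2),
    ml_mm = rep(c(-4.5, 4.5), each = 5),
    stringsAsFactors = FALSE
  )
}

#' Default SWD harmonic amplitudes
#'
#' Phase-aligned harmonics with geometrically decaying amplitudes; their sum
#' is a periodized pulse, i.e. one sharp spike riding on a slow wave per
#' cycle, which is the spike-wave morphology proxy used throughout.
#'
#' @param n_harmonics number of harmonics of the fundamental.
#' @param decay geometric decay ratio between successive harmonics.
#' @return numeric vector of relative amplitudes (fundamental first).
#' @export
swd_harmonics <- function(n_harmonics = 8, decay = 0.58) {
  decay^(seq_len(n_harmonics) - 1)
}

#' Session configuration for the synthetic generator
#'
#' Defaults reproduce the study conditions: 5 kHz sampling, ten electrodes in
#' two hemispheric rows, a baseline SWD rate of 62.2 events/hour and mean
#' duration 24.8 s (SD 2.7 s), a 7 Hz fundamental, and an in-band
#' (6-8 Hz) ictal-to-interictal amplitude ratio of 10.
#'
#' @param fs sampling rate, Hz.
#' @param duration session length, seconds.
#' @param layout electrode table as from [default_layout()]; must have equal
#'   channel counts per hemisphere.
#' @param swd_rate SWD events per hour (Poisson rate).
#' @param swd_duration_mean,swd_duration_sd event duration distribution
#'   (seconds); durations are normal truncated to `duration_range`.
#' @param duration_range truncation bounds for event durations, seconds.
#' @param f0 SWD fundamental frequency, Hz (must lie in [4, 20] so it falls
#'   on the analysis grid).
#' @param harmonic_amps relative amplitudes of the f0 harmonics.
#' @param amp_jitter log-SD of the slow multiplicative amplitude envelope.
#' @param phase_jitter SD (radians) of the slow random phase modulation;
#'   independent waveform copies decorrelate when this is of order 1.
#' @param background_exponent beta of the 1/f^beta background.
#' @param coupling background inter-channel magnitude-squared coherence
#'   target in [0, 1].
#' @param swd_coupling coherence target for the SWD component; SWDs are
#'   hyper-synchronous, so ictal coherence exceeds the background level.
#'   The effective ictal coupling is `max(coupling, swd_coupling)`.
#' @param snr_amplitude ictal/interictal amplitude ratio in the 6-8 Hz band
#'   (power ratio is its square).
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#' @return An object of class `session_config`.
#' @export
session_config <- function(fs = 5000, duration = 3600,
                           layout = default_layout(),
                           swd_rate = 62.2,
                           swd_duration_mean = 24.8, swd_duration_sd = 2.7,
                           duration_range = c(5, 60),
                           f0 = 7, harmonic_amps = swd_harmonics(),
                           amp_jitter = 0.2, phase_jitter = 1.5,
                           background_exponent = 1, coupling = 0.4,
                           swd_coupling = 0.95,
                           snr_amplitude = 10, seed = NULL) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (swd_rate < 0) stop("swd_rate must be >= 0", call. = FALSE)
  if (f0 < 4 || f0 > 20)
    stop("f0 must lie within [4, 20] (the analysis grid)", call. = FALSE)
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]",
                                         call. = FALSE)
  if (swd_coupling < 0 || swd_coupling > 1)
    stop("swd_coupling must be in [0, 1]", call. = FALSE)
  counts <- table(layout$hemisphere)
  if (length(counts) == 2L && counts[1] != counts[2])
    stop("layout must have equal channel counts per hemisphere", call. = FALSE)
  if (anyDuplicated(layout$label))
    stop("channel labels must be unique", call. = FALSE)
  structure(list(fs = fs, duration = duration, layout = layout,
                 n_channels = nrow(layout),
                 swd_rate = swd_rate,
                 swd_duration_mean = swd_duration_mean,
                 swd_duration_sd = swd_duration_sd,
                 duration_range = duration_range,
                 f0 = f0, harmonic_amps = harmonic_amps,
                 amp_jitter = amp_jitter, phase_jitter = phase_jitter,
                 background_exponent = background_exponent,
                 coupling = coupling, swd_coupling = swd_coupling,
                 snr_amplitude = snr_amplitude,
                 seed = seed),
            class = "session_config")
}

#' Treatment effect specification
#'
#' Describes the electrophysiological signature injected on a subset of
#' channels: SWD power in a band multiplied by `power_scale` (a value of 0.6
#' is a 40% power reduction) and the shared SWD component between target
#' channels partially replaced by independent copies (`coherence_drop`).
#'
#' @param target_channels character vector of channel labels, or NULL for
#'   all left-hemisphere channels.
#' @param power_scale multiplicative factor on in-band SWD power (>= 0).
#' @param coherence_drop fraction of the shared SWD component replaced by
#'   independent copies on target channels, in [0, 1].
#' @param band frequency band (Hz) affected by `power_scale`.
#' @param onset_session index of the first affected session in a
#'   multi-session experiment (default 2: the baseline session is never
#'   affected).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_channels = NULL, power_scale = 1,
                        coherence_drop = 0, band = c(6, 8),
                        onset_session = 2L) {
  if (power_scale < 0) stop("power_scale must be >= 0", call. = FALSE)
  if (coherence_drop < 0 || coherence_drop > 1)
    stop("coherence_drop must be in [0, 1]", call. = FALSE)
  structure(list(target_channels = target_channels,
                 power_scale = power_scale,
                 coherence_drop = coherence_drop,
                 band = band, onset_session = onset_session),
            class = "effect_spec")
}

## Ornstein-Uhlenbeck process with stationary SD 1, correlation time tau (s),
## vectorized through the recursive filter.
ou_process <- function(n, fs, tau) {
  a <- exp(-1 / (fs * tau))
  innov <- stats::rnorm(n) * sqrt(1 - a^2)
  innov[1] <- stats::rnorm(1)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

## Gaussian 1/f^beta noise, unit variance, spectrum flattened below f_min
## to keep the variance finite.
colored_noise <- function(n, fs, beta = 1, f_min = 0.5) {
  x <- stats::rnorm(n)
  if (beta == 0) return(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_sym <- pmin(f, fs - f)
  H <- pmax(f_sym, f_min)^(-beta / 2)
  H[1] <- 0
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n
  y / stats::sd(y)
}

## Harmonic carriers for one SWD realization: a slow lognormal amplitude
## envelope g(t) times cos(k * Theta(t)), Theta = 2 pi f0 t + phase jitter.
## Returns an n x K matrix; the waveform is carriers %*% amps.
## Phase jitter needs a differentiable sample path: raw OU noise has
## Lorentzian spectral wings that leak harmonic power across the whole band,
## so the OU process is smoothed by a second exponential filter and
## restandardized.
smooth_jitter <- function(n, fs, tau, tau2 = 0.05) {
  z <- ou_process(n, fs, tau)
  a2 <- exp(-1 / (fs * tau2))
  z2 <- as.numeric(stats::filter(z * (1 - a2), a2, method = "recursive"))
  s <- stats::sd(z2)
  if (!is.finite(s) || s == 0) return(rep(0, n))
  z2 / s
}

swd_carriers <- function(n, fs, f0, n_harmonics, amp_jitter, phase_jitter,
                         phase_tau = 0.2) {
  t <- (seq_len(n) - 1) / fs
  phi <- if (phase_jitter > 0)
    phase_jitter * smooth_jitter(n, fs, phase_tau) else 0
  g <- if (amp_jitter > 0)
    exp(amp_jitter * smooth_jitter(n, fs, 0.3) - amp_jitter^2 / 2) else 1
  theta <- 2 * pi * f0 * t + phi
  k_max <- max(1L, min(n_harmonics, floor((fs / 2 * 0.95) / f0)))
  carriers <- vapply(seq_len(k_max), function(k) g * cos(k * theta),
                     numeric(n))
  carriers
}

#' Generate one SWD waveform
#'
#' A stochastic narrowband process: phase-aligned harmonics of `f0` with
#' decaying amplitudes (their sum is a periodized pulse, one sharp spike per
#' cycle) modulated by a slow lognormal amplitude envelope and slow random
#' phase jitter. Harmonics above Nyquist are dropped.
#'
#' @param duration_s waveform length, seconds (> 0).
#' @param f0 fundamental frequency, Hz (> 0).
#' @param harmonic_amps relative harmonic amplitudes, fundamental first.
#' @param fs sampling rate, Hz.
#' @param seed optional RNG seed.
#' @param amp_jitter,phase_jitter envelope log-SD and phase SD (radians);
#'   the standalone default keeps phase jitter small so the periodogram peak
#'   sits exactly at `f0`.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @examples
#' w <- swd_waveform(2, 7, fs = 1000, seed = 1)
#' @export
swd_waveform <- function(duration_s, f0, harmonic_amps = swd_harmonics(),
                         fs = 5000, seed = NULL,
                         amp_jitter = 0.2, phase_jitter = 0.25) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  carriers <- swd_carriers(n, fs, f0, length(harmonic_amps),
                           amp_jitter, phase_jitter)
  amps <- harmonic_amps[seq_len(ncol(carriers))]
  as.numeric(carriers %*% amps)
}

## Draw a duration from N(mean, sd) truncated to range.
rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 4, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

## Place n_events non-overlapping events. Each event needs a clean
## pre-onset epoch (baseline windows and interictal segments) and a spectral
## margin after its analysis window, so events keep a minimum gap of gap_s
## and stay pre_s from the session start / post_s from its end.
## Collisions are redrawn; if bounded retries fail but the events still fit,
## the layout falls back to sequential placement with the slack distributed
## as uniform spacings.
place_events <- function(n_events, durations, session_s, pre_s = 2.5,
                         post_s = 2.5, gap_s = 2, max_tries = 500) {
  lo <- 0.1 * durations + pre_s
  if (any(session_s - durations - 0.1 * durations - post_s <= lo))
    stop("session too short to place an event of duration ",
         round(max(durations), 1), " s", call. = FALSE)
  onsets <- numeric(0); offsets <- numeric(0)
  ok <- TRUE
  for (i in seq_len(n_events)) {
    d <- durations[i]
    hi <- session_s - d - 0.1 * d - post_s
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      on <- stats::runif(1, lo[i], hi)
      off <- on + d
      if (!any(on < offsets + gap_s & off > onsets - gap_s)) {
        onsets <- c(onsets, on); offsets <- c(offsets, off)
        placed <- TRUE
        break
      }
    }
    if (!placed) { ok <- FALSE; break }
  }
  if (!ok) {
    ## sequential fallback: feasible iff total footprint fits
    slack <- session_s - sum(durations + gap_s) - pre_s - post_s -
      0.1 * durations[1] - 0.1 * durations[n_events]
    if (slack < 0)
      stop("could not place ", n_events, " non-overlapping events after ",
           max_tries, " retries (rate too high for session length)",
           call. = FALSE)
    w <- stats::rexp(n_events + 1)
    gaps <- slack * w / sum(w)
    onsets <- numeric(n_events)
    cursor <- pre_s + 0.1 * durations[1]
    for (i in seq_len(n_events)) {
      cursor <- cursor + gaps[i]
      onsets[i] <- cursor
      cursor <- cursor + durations[i] + gap_s
    }
    offsets <- onsets + durations
  }
  ord <- order(onsets)
  data.frame(onset_s = onsets[ord], offset_s = offsets[ord])
}

## In-band power of a trace from its periodogram (mean PSD x bandwidth).
band_power_periodogram <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  psd <- (Mod(X)^2) / (fs * n)
  sel <- f >= band[1] & f <= band[2]
  2 * mean(psd[sel]) * diff(band)
}

#' Generate a synthetic multi-channel LFP session
#'
#' Composes a 1/f background (with an inter-channel shared component set by
#' `coupling`), and SWD bursts inserted on all channels during events drawn
#' from a Poisson process with truncated-normal durations. The SWD amplitude
#' is calibrated numerically each session so the 6-8 Hz ictal/interictal
#' amplitude ratio equals `snr_amplitude`. With an [effect_spec()], in-band
#' SWD power on target channels is multiplied by `power_scale` and a fraction
#' `coherence_drop` of the shared SWD component is replaced by independent
#' copies.
#'
#' @param config a [session_config()].
#' @param effect an [effect_spec()] or NULL.
#' @param n_events fixed number of events, or NULL to draw from the Poisson
#'   process at `config$swd_rate`.
#' @param min_gap_s minimum gap between consecutive events, seconds; raise
#'   it (e.g. to 15) when the session is destined for map analysis, which
#'   needs a clean pre-onset baseline epoch for every event.
#' @param edge_pre_s clear time required before the first event's analysis
#'   window (seconds from session start).
#' @return list with `recording` (a [swd_recording()]) and `events`
#'   (data.frame `onset_s`, `offset_s`), the exact ground truth.
#' @export
generate_session <- function(config, effect = NULL, n_events = NULL,
                             min_gap_s = 2, edge_pre_s = 2.5) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(effect)) stopifnot(inherits(effect, "effect_spec"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  n_ch <- config$n_channels
  layout <- config$layout

  ## --- events ---------------------------------------------------------
  if (is.null(n_events))
    n_events <- stats::rpois(1, config$swd_rate * config$duration / 3600)
  events <- if (n_events > 0) {
    durs <- rtrunc_norm(n_events, config$swd_duration_mean,
                        config$swd_duration_sd, config$duration_range)
    place_events(n_events, durs, config$duration, pre_s = edge_pre_s,
                 gap_s = min_gap_s)
  } else data.frame(onset_s = numeric(0), offset_s = numeric(0))

  ## --- amplitude calibration ------------------------------------------
  ## reference realizations of waveform and background give the scale that
  ## sets the in-band (6-8 Hz) amplitude SNR. They come from a private,
  ## fixed RNG stream so the scale is a function of the parameters only:
  ## a per-session random scale would correlate every seizure of a session
  ## and undermine the fixed-effects pooling the analysis assumes.
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  rng_state <- get(".Random.seed", envir = globalenv())
  set.seed(62271L)
  ref_n <- round(60 * fs)
  ref_carr <- swd_carriers(ref_n, fs, config$f0, length(config$harmonic_amps),
                           config$amp_jitter, config$phase_jitter)
  ref_w <- as.numeric(ref_carr %*%
                        config$harmonic_amps[seq_len(ncol(ref_carr))])
  ref_bg <- colored_noise(ref_n, fs, config$background_exponent)
  assign(".Random.seed", rng_state, envir = globalenv())
  band <- c(6, 8)
  p_w <- band_power_periodogram(ref_w, fs, band)
  p_b <- band_power_periodogram(ref_bg, fs, band)
  swd_scale <- config$snr_amplitude * sqrt(p_b / p_w)

  ## --- background ------------------------------------------------------
  ## shared variance fraction p gives magnitude-squared coherence p^2
  p_sh <- sqrt(config$coupling)
  p_swd <- sqrt(max(config$coupling, config$swd_coupling %||% 0.95))
  shared_bg <- colored_noise(n, fs, config$background_exponent)
  samples <- matrix(0, nrow = n_ch, ncol = n)
  for (ch in seq_len(n_ch)) {
    samples[ch, ] <- sqrt(p_sh) * shared_bg +
      sqrt(1 - p_sh) * colored_noise(n, fs, config$background_exponent)
  }

  ## --- SWD insertion ---------------------------------------------------
  targets <- if (is.null(effect)) character(0) else {
    if (is.null(effect$target_channels))
      layout$label[layout$hemisphere == "left"]
    else effect$target_channels
  }
  n_harm <- length(config$harmonic_amps)
  if (nrow(events) > 0) {
    for (ev in seq_len(nrow(events))) {
      i0 <- round(events$onset_s[ev] * fs) + 1L
      len <- round((events$offset_s[ev] - events$onset_s[ev]) * fs)
      idx <- i0:(i0 + len - 1L)
      sh <- swd_carriers(len, fs, config$f0, n_harm,
                         config$amp_jitter, config$phase_jitter)
      k_max <- ncol(sh)
      amps <- config$harmonic_amps[seq_len(k_max)]
      harm_f <- seq_len(k_max) * config$f0
      taper <- event_taper(len, fs)
      for (ch in seq_len(n_ch)) {
        is_target <- layout$label[ch] %in% targets
        amps_ch <- amps
        if (is_target && effect$power_scale != 1) {
          in_band <- harm_f >= effect$band[1] & harm_f <= effect$band[2]
          amps_ch[in_band] <- amps_ch[in_band] * sqrt(effect$power_scale)
        }
        d <- if (is_target) effect$coherence_drop else 0
        ind <- swd_carriers(len, fs, config$f0, n_harm,
                            config$amp_jitter, config$phase_jitter)
        w_sh <- as.numeric(sh %*% amps_ch)
        w_ind <- as.numeric(ind %*% amps_ch)
        if (d > 0) {
          ind2 <- swd_carriers(len, fs, config$f0, n_harm,
                               config$amp_jitter, config$phase_jitter)
          w_sh <- sqrt(1 - d) * w_sh +
            sqrt(d) * as.numeric(ind2 %*% amps_ch)
        }
        w_ch <- sqrt(p_swd) * w_sh + sqrt(1 - p_swd) * w_ind
        samples[ch, idx] <- samples[ch, idx] + swd_scale * taper * w_ch
      }
    }
  }

  rec <- swd_recording(samples, fs, layout)
  list(recording = rec, events = events)
}

## Short cosine onset/offset ramp so event edges are abrupt (SWDs start
## within a cycle) but not discontinuous.
event_taper <- function(len, fs, ramp_s = 0.05) {
  ramp <- min(round(ramp_s * fs), floor(len / 4))
  taper <- rep(1, len)
  if (ramp > 1) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    taper[seq_len(ramp)] <- up
    taper[len - ramp + seq_len(ramp)] <- rev(up)
  }
  taper
}
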