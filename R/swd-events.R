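#' SWD spike and event detection
#'
#' Spikes are threshold crossings of the rectified trace; an SWD event is a
#' run of spikes with small gaps, and its onset/offset are the first and last
#' spike times. Each event's analysis window extends the event by 10% of its
#' duration on both sides; events whose window leaves the recording are
#' excluded rather than clipped.
#'
#' @name swd-events
NULL

#' Detect spikes in a single trace
#'
#' Local maxima of the rectified signal exceeding `threshold_sd` robust
#' standard deviations (median absolute deviation scaled by 1.4826, so large
#' spikes do not inflate the threshold), separated by at least `min_isi_ms`.
#' When two candidate peaks fall closer than that, the larger one wins.
#'
#' @param trace numeric vector (non-empty).
#' @param fs sampling rate, Hz.
#' @param threshold_sd threshold in robust SD units (> 0).
#' @param min_isi_ms minimum inter-spike interval, milliseconds (> 0).
#' @param threshold_abs absolute threshold (same units as the trace); when
#'   given it overrides `threshold_sd`, e.g. to reuse a whole-session
#'   threshold on an ictal excerpt whose own robust SD is inflated.
#' @return spike times in seconds (time 0 = first sample).
#' @export
detect_spikes <- function(trace, fs, threshold_sd = 4, min_isi_ms = 40,
                          threshold_abs = NULL) {
  if (length(trace) == 0) stop("empty trace", call. = FALSE)
  if (threshold_sd <= 0) stop("threshold_sd must be > 0", call. = FALSE)
  if (min_isi_ms <= 0) stop("min_isi_ms must be > 0", call. = FALSE)
  x <- abs(trace - stats::median(trace))
  thr <- threshold_abs %||% (threshold_sd * stats::mad(trace))
  if (thr == 0) return(numeric(0))
  n <- length(x)
  if (n < 3) return(numeric(0))
  core <- x[2:(n - 1)]
  is_peak <- core >= x[1:(n - 2)] & core > x[3:n] & core > thr
  peaks <- which(is_peak) + 1L
  if (length(peaks) == 0) return(numeric(0))
  ## greedy suppression: keep peaks in decreasing height order, drop any
  ## candidate within min_isi of an already kept peak
  min_gap <- min_isi_ms / 1000 * fs
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept - 1L) / fs
}

#' Group spikes into SWD events
#'
#' Spikes separated by at most `max_gap_s` belong to one run; runs spanning
#' at least `min_duration_s` become events whose onset and offset are the
#' first and last spike of the run.
#'
#' @param spike_times sorted spike times, seconds.
#' @param max_gap_s largest within-event inter-spike gap, seconds.
#' @param min_duration_s shortest admitted event, seconds.
#' @return data.frame `onset_s`, `offset_s` (possibly empty).
#' @export
events_from_spikes <- function(spike_times, max_gap_s = 1,
                               min_duration_s = 2) {
  if (length(spike_times) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  if (is.unsorted(spike_times)) stop("spike_times must be sorted",
                                     call. = FALSE)
  brk <- c(0, which(diff(spike_times) > max_gap_s), length(spike_times))
  ev <- lapply(seq_len(length(brk) - 1), function(i) {
    grp <- spike_times[(brk[i] + 1):brk[i + 1]]
    c(grp[1], grp[length(grp)])
  })
  ev <- do.call(rbind, ev)
  keep <- (ev[, 2] - ev[, 1]) >= min_duration_s
  data.frame(onset_s = ev[keep, 1], offset_s = ev[keep, 2])
}

#' Adaptive analysis window for one event
#'
#' The window starts 10% of the event duration before onset and ends 10%
#' after offset. Events whose window would leave the recording (optionally
#' including an extra margin needed by the spectral estimator) are flagged
#' unanalyzable and must be excluded, not clipped.
#'
#' @param onset_s,offset_s event boundaries, seconds (offset > onset).
#' @param recording_duration recording length, seconds.
#' @param margin_s extra margin required outside the window (e.g. half the
#'   spectral window length), seconds.
#' @return list `t0`, `t1`, `analyzable` (logical).
#' @export
analysis_window <- function(onset_s, offset_s, recording_duration,
                            margin_s = 0) {
  if (offset_s <= onset_s)
    stop("event offset must exceed onset", call. = FALSE)
  d <- offset_s - onset_s
  t0 <- onset_s - 0.1 * d
  t1 <- offset_s + 0.1 * d
  ok <- (t0 - margin_s) >= 0 && (t1 + margin_s) <= recording_duration
  list(t0 = t0, t1 = t1, analyzable = ok)
}

#' Detect SWD events on one channel
#'
#' Candidate regions are proposed by a hysteresis gate on sliding 6-8 Hz
#' band power (entered above `enter_factor` times the session median band
#' power, left below `exit_factor` times it), then refined by spike
#' detection: onset and offset are the first and last spike inside the gated
#' region.
#'
#' @param trace numeric vector.
#' @param fs sampling rate, Hz.
#' @param band gating band, Hz.
#' @param window_s band-power window length, seconds.
#' @param enter_factor,exit_factor hysteresis thresholds relative to the
#'   median band power.
#' @param threshold_sd,min_isi_ms passed to [detect_spikes()].
#' @param max_gap_s,min_duration_s passed to [events_from_spikes()].
#' @return data.frame `onset_s`, `offset_s`.
#' @export
detect_swd_events <- function(trace, fs, band = c(6, 8), window_s = 1,
                              enter_factor = 8, exit_factor = 3,
                              threshold_sd = 4, min_isi_ms = 40,
                              max_gap_s = 1, min_duration_s = 2) {
  if (length(trace) < window_s * fs) stop("trace too short", call. = FALSE)
  win <- round(window_s * fs)
  hop <- max(1L, round(win / 4))
  starts <- seq(1L, length(trace) - win + 1L, by = hop)
  bp <- vapply(starts, function(s)
    band_power_periodogram(trace[s:(s + win - 1L)], fs, band), numeric(1))
  med <- stats::median(bp)
  thr_abs <- threshold_sd * stats::mad(trace)
  if (med == 0) return(data.frame(onset_s = numeric(0),
                                  offset_s = numeric(0)))
  ## hysteresis gate over the window sequence
  state <- FALSE
  gate <- logical(length(bp))
  for (i in seq_along(bp)) {
    state <- if (state) bp[i] > exit_factor * med
             else bp[i] > enter_factor * med
    gate[i] <- state
  }
  if (!any(gate)) return(data.frame(onset_s = numeric(0),
                                    offset_s = numeric(0)))
  runs <- rle(gate)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    a <- max(1, (starts[begins[r]] - 1) / fs - window_s)
    b <- min(length(trace) / fs,
             (starts[ends[r]] - 1 + win) / fs + window_s)
    seg <- trace[(round(a * fs) + 1):round(b * fs)]
    sp <- detect_spikes(seg, fs, threshold_sd, min_isi_ms,
                        threshold_abs = thr_abs) + a
    ev <- events_from_spikes(sp, max_gap_s, min_duration_s)
    if (nrow(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(data.frame(onset_s = numeric(0),
                                      offset_s = numeric(0)))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  ## merge events split across adjacent gated runs
  merged <- ev[1, ]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$onset_s[i] <= merged$offset_s[nrow(merged)] + max_gap_s)
        merged$offset_s[nrow(merged)] <-
          max(merged$offset_s[nrow(merged)], ev$offset_s[i])
      else merged <- rbind(merged, ev[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Consensus events across channels
#'
#' Intervals where at least `min_frac` of all channels report an event are
#' merged into consensus events (union of agreeing per-channel intervals).
#'
#' @param event_lists list of per-channel event data.frames.
#' @param min_frac minimum fraction of channels that must agree.
#' @param min_duration_s shortest admitted consensus event, seconds.
#' @return data.frame `onset_s`, `offset_s`.
#' @export
consensus_events <- function(event_lists, min_frac = 0.5,
                             min_duration_s = 2) {
  n_ch <- length(event_lists)
  if (n_ch == 0) return(data.frame(onset_s = numeric(0),
                                   offset_s = numeric(0)))
  edges <- sort(unique(unlist(lapply(event_lists, function(e)
    c(e$onset_s, e$offset_s)))))
  if (length(edges) < 2) return(data.frame(onset_s = numeric(0),
                                           offset_s = numeric(0)))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cover <- vapply(mids, function(m) {
    sum(vapply(event_lists, function(e)
      any(e$onset_s <= m & m < e$offset_s), logical(1)))
  }, numeric(1))
  ok <- cover >= min_frac * n_ch
  if (!any(ok)) return(data.frame(onset_s = numeric(0),
                                  offset_s = numeric(0)))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  ev <- do.call(rbind, lapply(which(runs$values), function(r)
    c(edges[begins[r]], edges[ends[r] + 1])))
  keep <- (ev[, 2] - ev[, 1]) >= min_duration_s
  data.frame(onset_s = ev[keep, 1], offset_s = ev[keep, 2])
}
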