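#' End-to-end analysis pipeline
#'
#' Orchestrates the full analysis on synthetic sessions: simulate, map each
#' seizure's power (or coherence) on the 4-20 Hz sliding-Welch grid,
#' normalize to the pre-event baseline, rescale seizure time, smooth, pool
#' across animals and seizures, run RFT-corrected inference per channel, and
#' reduce to 6-8 Hz band summaries with repeated-measures statistics.
#'
#' @name pipeline
NULL

#' Adjacent within-hemisphere electrode pairs
#'
#' @param layout electrode table.
#' @return character vector of pair ids `"A-B"`, adjacent along the
#'   anteroposterior row of each hemisphere.
#' @export
adjacent_pairs <- function(layout = default_layout()) {
  unlist(lapply(split(layout, layout$hemisphere), function(h) {
    h <- h[order(h$ap_mm, decreasing = TRUE), ]
    paste(h$label[-nrow(h)], h$label[-1], sep = "-")
  }), use.names = FALSE)
}

#' Normalized, rescaled, smoothed maps for a session's events
#'
#' For every analyzable event (its 10% window plus the spectral margin must
#' fit in the recording): estimate the sliding Welch map, z-score against
#' the pre-onset baseline, rescale time to the common seizure axis, and
#' smooth. Events whose window leaves the recording are skipped.
#'
#' The baseline statistics use only map bins whose full 4 s spectral window
#' lies before the seizure onset: a window centred inside the nominal 10%
#' pre-SWD margin would overlap the discharge itself, which inflates the
#' baseline SD in proportion to ictal power and cancels the very power
#' differences under test. The map grid therefore starts two window lengths
#' before the nominal window start (so the baseline SD has enough effective
#' degrees of freedom despite the heavy window overlap), and baseline bins
#' are the window centres in `[t0 - 3 window_s, onset - window_s/2]`.
#' Events whose baseline epoch overlaps a neighbouring event are skipped.
#'
#' @param session list with `recording` and `events` (as from
#'   [generate_session()]).
#' @param channels channel labels (power) or pair ids `"A-B"` (coherence).
#' @param measure `"power"` or `"coherence"`.
#' @param n_bins rescaled time bins.
#' @param fwhm_time_fraction,fwhm_freq_hz smoothing FWHMs.
#' @param freqs frequency axis.
#' @param meta named list merged into each map's metadata (e.g. `animal`,
#'   `timepoint`, `condition`).
#' @return list of smoothed [tf_map()]s.
#' @export
session_event_maps <- function(session, channels,
                               measure = c("power", "coherence"),
                               n_bins = 121,
                               fwhm_time_fraction = 0.05, fwhm_freq_hz = 5,
                               freqs = seq(4, 20, by = 0.1),
                               meta = list()) {
  measure <- match.arg(measure)
  rec <- session$recording
  events <- session$events
  rec_dur <- ncol(rec$samples) / rec$fs
  maps <- list()
  window_s <- 4
  for (ev in seq_len(nrow(events))) {
    on <- events$onset_s[ev]; off <- events$offset_s[ev]
    win <- analysis_window(on, off, rec_dur, margin_s = window_s / 2 + 0.1)
    g0 <- win$t0 - 3 * window_s               # extra pre-onset baseline span
    if (!win$analyzable || g0 - window_s / 2 - 0.1 < 0) next
    ## the baseline epoch must itself be interictal
    others <- events[-ev, , drop = FALSE]
    if (any(others$offset_s > g0 - window_s / 2 & others$onset_s < on)) next
    n_steps <- ceiling((win$t1 - g0) / 0.1 - 1e-9)
    grid <- tf_grid(g0, g0 + 0.1 * n_steps, freqs = freqs,
                    window_s = window_s)
    for (ch in channels) {
      m <- if (measure == "power") {
        sliding_welch_power(channel_trace(rec, ch), rec$fs, grid,
                            channel = ch, event_id = ev)
      } else {
        labs <- strsplit(ch, "-", fixed = TRUE)[[1]]
        sliding_welch_coherence(channel_trace(rec, labs[1]),
                                channel_trace(rec, labs[2]),
                                rec$fs, grid, channel = ch, event_id = ev)
      }
      m <- normalize_map(m, c(g0, on - window_s / 2))
      m <- rescale_time(m, on, off, n_bins = n_bins)
      m <- smooth_map(m, fwhm_time_fraction, fwhm_freq_hz)
      m$meta <- utils::modifyList(m$meta, meta)
      maps[[length(maps) + 1L]] <- m
    }
  }
  maps
}

#' Simulate a pre/post experiment and compute its seizure maps
#'
#' One session per animal and condition, a fixed number of seizures per
#' session, the effect applied in the post condition only. Returns the
#' smoothed maps (with animal/condition metadata) ready for
#' [pool_fixed_effects()] and [band_summary()], plus the ground-truth
#' events.
#'
#' @param n_animals animals per condition.
#' @param seizures_per_session events per session.
#' @param effect [effect_spec()] applied post.
#' @param channels channels (or pairs) to map.
#' @param measure `"power"` or `"coherence"`.
#' @param fs sampling rate for the synthetic sessions, Hz.
#' @param session_s session length, seconds (must hold the requested
#'   events).
#' @param timepoints condition labels; the first is the baseline ("pre").
#' @param seed RNG seed for the whole experiment.
#' @param config_args extra arguments passed to [session_config()].
#' @return list `maps`, `events` (per session), `layout`.
#' @export
simulate_experiment <- function(n_animals = 4, seizures_per_session = 5,
                                effect = effect_spec(),
                                channels = central_electrodes(),
                                measure = "power",
                                fs = 200, session_s = 400,
                                timepoints = c("baseline", "1w"),
                                seed = NULL,
                                config_args = list()) {
  if (!is.null(seed)) set.seed(seed)
  maps <- list(); events <- list()
  layout <- do.call(session_config,
                    c(list(fs = fs, duration = session_s),
                      config_args))$layout
  for (a in seq_len(n_animals)) {
    for (ti in seq_along(timepoints)) {
      tp <- timepoints[ti]
      cfg <- do.call(session_config,
                     c(list(fs = fs, duration = session_s,
                            seed = sample.int(.Machine$integer.max, 1)),
                       config_args))
      eff <- if (ti >= (effect$onset_session %||% 2)) effect else NULL
      ses <- generate_session(cfg, effect = eff,
                              n_events = seizures_per_session,
                              min_gap_s = 15, edge_pre_s = 15)
      mm <- session_event_maps(
        ses, channels, measure,
        meta = list(animal = paste0("A", a), timepoint = tp,
                    condition = if (ti == 1) "pre" else "post"))
      maps <- c(maps, mm)
      events[[paste(a, tp, sep = "_")]] <- ses$events
    }
  }
  list(maps = maps, events = events, layout = layout)
}

#' Run the complete pipeline and write results
#'
#' Simulates a two-condition experiment, runs per-channel RFT inference and
#' band statistics, computes the transection geometry, and writes plain-text
#' results (CSV tables and a JSON summary) to `out_dir`. Deterministic for a
#' fixed `seed`.
#'
#' @param config named list; recognized entries (with defaults):
#'   `seed` (1), `fs` (200), `n_animals` (4), `seizures_per_session` (5),
#'   `session_s` (400), `alpha` (0.05), `band` (c(6, 8)),
#'   `power_scale` (0.6), `coherence_drop` (0.5), `measure` ("power").
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `stat` (per-channel [rft_inference()]
#'   results), `summary` (band summary rows), `anova` and `geometry`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  defaults <- list(seed = 1, fs = 200, n_animals = 4,
                   seizures_per_session = 5, session_s = 400,
                   alpha = 0.05, band = c(6, 8), power_scale = 0.6,
                   coherence_drop = 0.5, measure = "power")
  cfg <- utils::modifyList(defaults, config)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$n_animals < 2)
    stop("config error: need >= 2 animals", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(cfg$seed)
  eff <- effect_spec(power_scale = cfg$power_scale,
                     coherence_drop = cfg$coherence_drop, band = cfg$band)
  channels <- central_electrodes()
  exper <- simulate_experiment(
    n_animals = cfg$n_animals,
    seizures_per_session = cfg$seizures_per_session,
    effect = eff, channels = channels, measure = cfg$measure,
    fs = cfg$fs, session_s = cfg$session_s,
    seed = sample.int(.Machine$integer.max, 1))

  for (nm in names(exper$events))
    write_events(exper$events[[nm]],
                 file.path(out_dir, paste0("events_", nm, ".csv")))

  stats_by_ch <- list()
  for (ch in channels) {
    sel <- Filter(function(m) identical(m$channel, ch), exper$maps)
    pooled <- pool_fixed_effects(sel)
    stats_by_ch[[ch]] <- rft_inference(
      pooled, fwhm_bins_t = sel[[1]]$meta$fwhm_bins_t,
      fwhm_bins_f = sel[[1]]$meta$fwhm_bins_f, alpha = cfg$alpha)
  }
  sig_tab <- data.frame(
    channel = names(stats_by_ch),
    u_star = vapply(stats_by_ch, function(s) s$u_star, numeric(1)),
    n_sig_pixels = vapply(stats_by_ch, function(s) sum(s$sig_mask),
                          numeric(1)))
  utils::write.csv(sig_tab, file.path(out_dir, "rft_summary.csv"),
                   row.names = FALSE)

  summ <- band_summary(exper$maps, band = cfg$band)
  utils::write.csv(summ, file.path(out_dir, "band_summary.csv"),
                   row.names = FALSE)
  an <- rm_anova_2way(summ)
  utils::write.csv(an$posthoc, file.path(out_dir, "band_posthoc.csv"),
                   row.names = FALSE)

  plan <- transection_plan()
  fp <- intersection_footprint(plan$port_angles_deg, plan$beam_height_mm)
  geometry <- list(
    thickness_um = interlaced_thickness(length(plan$port_angles_deg),
                                        plan$beam_width_um, plan$step_um),
    min_caliper_width_mm = fp$min_caliper_width_mm,
    max_diameter_mm = fp$max_diameter_mm,
    n_vertices = fp$n_vertices)
  jsonlite::write_json(
    c(geometry, list(seed = cfg$seed, alpha = cfg$alpha)),
    file.path(out_dir, "geometry.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(stat = stats_by_ch, summary = summ, anova = an,
                 geometry = geometry))
}
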