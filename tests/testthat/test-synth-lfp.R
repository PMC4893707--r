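test_that("SWD waveform peaks at the fundamental with one spike per cycle", {
  fs <- 200
  w <- swd_waveform(25, 7, fs = fs, seed = 1)
  expect_length(w, 25 * fs)
  X <- Mod(stats::fft(w))^2
  f <- (seq_along(w) - 1) * fs / length(w)
  sel <- f > 0 & f <= fs / 2
  expect_equal(f[sel][which.max(X[sel])], 7)
  # spike count equals the cycle count of the generated trace
  n_spikes <- length(detect_spikes(w, fs))
  expect_lte(abs(n_spikes - round(25 * 7)), 1)
  # jitter-free waveform: one spike per cycle (the peak of the cycle
  # starting at t = 0 sits on the first sample and cannot be a local max)
  w0 <- swd_waveform(25, 7, fs = fs, seed = 2, amp_jitter = 0,
                     phase_jitter = 0)
  expect_lte(abs(length(detect_spikes(w0, fs)) - 175), 1)
})

test_that("single-harmonic waveform is a pure sinusoid", {
  fs <- 200
  w <- swd_waveform(10, 7, harmonic_amps = 1, fs = fs, seed = 3,
                    amp_jitter = 0, phase_jitter = 0)
  X <- Mod(stats::fft(w))^2 / length(w)
  f <- (seq_along(w) - 1) * fs / length(w)
  p7 <- X[which.min(abs(f - 7))]
  p14 <- X[which.min(abs(f - 14))]
  expect_lt(p14 / p7, 1e-20)
})

test_that("waveform rejects invalid parameters", {
  expect_error(swd_waveform(0, 7, fs = 100), "duration")
  expect_error(swd_waveform(10, -1, fs = 100), "f0")
  expect_error(session_config(f0 = 2), "4, 20")
  expect_error(session_config(fs = -1), "fs")
  expect_error(effect_spec(power_scale = -1), "power_scale")
  expect_error(effect_spec(coherence_drop = 2), "coherence_drop")
})

test_that("sessions are bit-identical under a fixed seed", {
  mk <- function() generate_session(
    session_config(fs = 100, duration = 300, seed = 7), n_events = 4)
  a <- mk(); b <- mk()
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
})

test_that("zero rate gives a background-only session", {
  ses <- generate_session(session_config(fs = 100, duration = 60,
                                         swd_rate = 0, seed = 1))
  expect_equal(nrow(ses$events), 0)
  expect_equal(dim(ses$recording$samples), c(10, 6000))
})

test_that("event counts are Poisson-consistent across sessions", {
  counts <- vapply(1:30, function(s) {
    nrow(generate_session(session_config(fs = 20, duration = 900,
                                         seed = 500 + s))$events)
  }, numeric(1))
  # index of dispersion against the chi-square null (99% interval)
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  expect_gt(disp, qchisq(0.005, 29))
  expect_lt(disp, qchisq(0.995, 29))
})

test_that("placement fails cleanly when events cannot fit", {
  expect_error(
    generate_session(session_config(fs = 50, duration = 120, seed = 1),
                     n_events = 10),
    "rate too high|too short")
})

test_that("power_scale reduces in-band ictal PSD by the stated factor", {
  bp_ratio <- local({
    num <- 0; den <- 0
    for (s in 1:3) {
      ses <- generate_session(
        session_config(fs = 100, duration = 450, seed = 300 + s),
        effect = effect_spec(power_scale = 0.36), n_events = 7)
      for (ev in seq_len(nrow(ses$events))) {
        on <- ses$events$onset_s[ev]; off <- ses$events$offset_s[ev]
        for (ch in 1:5) {
          num <- num + periodogram_band_power(
            channel_trace(ses$recording, paste0("L", ch), on + 1, off - 1),
            100, c(6, 8))
          den <- den + periodogram_band_power(
            channel_trace(ses$recording, paste0("R", ch), on + 1, off - 1),
            100, c(6, 8))
        }
      }
    }
    num / den
  })
  expect_lt(abs(bp_ratio - 0.36), 0.036)
})

test_that("coupling and coherence_drop drive ictal coherence as specified", {
  fs <- 200
  ses1 <- generate_session(
    session_config(fs = fs, duration = 300, coupling = 1, swd_coupling = 1,
                   seed = 3), n_events = 3)
  ev <- ses1$events
  g <- tf_grid(ev$onset_s[1] + 2, ev$offset_s[1] - 2)
  band <- function(m) mean(m$values[, m$freqs >= 6 & m$freqs <= 8])
  m <- sliding_welch_coherence(channel_trace(ses1$recording, "L2"),
                               channel_trace(ses1$recording, "R5"), fs, g)
  expect_gt(band(m), 0.99)

  ses2 <- generate_session(
    session_config(fs = fs, duration = 300, seed = 4),
    effect = effect_spec(coherence_drop = 1), n_events = 3)
  ev2 <- ses2$events
  g2 <- tf_grid(ev2$onset_s[1] + 2, ev2$offset_s[1] - 2)
  left <- band(sliding_welch_coherence(channel_trace(ses2$recording, "L2"),
                                       channel_trace(ses2$recording, "L3"),
                                       fs, g2))
  right <- band(sliding_welch_coherence(channel_trace(ses2$recording, "R2"),
                                        channel_trace(ses2$recording, "R3"),
                                        fs, g2))
  expect_lt(left, 0.4)        # toward the independent-noise floor
  expect_gt(right, 0.75)      # untouched hemisphere stays synchronous
})
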