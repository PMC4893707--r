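test_that("baseline z-scoring matches hand-computed values", {
  g <- tf_grid(0, 0.5)  # 6 time bins
  vals <- matrix(7, 6, length(g$freqs))
  vals[1:3, ] <- c(1, 3, 5)  # baseline bins: mean 3, sd 2
  m <- tf_map(vals, g, "power")
  z <- normalize_map(m, c(0, 0.25))
  expect_equal(z$kind, "z-power")
  expect_true(all(abs(z$values[4:6, ] - 2) < 1e-12))
  expect_error(normalize_map(z, c(0, 0.25)), "already")
})

test_that("degenerate baseline is rejected with the frequency named", {
  g <- tf_grid(0, 0.5)
  m <- tf_map(matrix(1, 6, length(g$freqs)), g, "power")
  expect_error(normalize_map(m, c(0, 0.25)), "SD = 0.*4 Hz|degenerate")
  expect_error(normalize_map(m, c(0, 0.1)), "at least 2")
})

test_that("z-scoring equals a brute-force per-frequency oracle", {
  set.seed(10)
  g <- tf_grid(0, 2)  # 21 time bins
  nt <- length(g$times); nf <- length(g$freqs)
  vals <- matrix(rexp(nt * nf), nt, nf)
  m <- tf_map(vals, g, "power")
  z <- normalize_map(m, c(0, 0.75))
  bl <- which(g$times < 0.75)
  oracle <- vals
  for (j in seq_len(nf)) {
    mu <- mean(vals[bl, j]); s <- sd(vals[bl, j])
    oracle[, j] <- (vals[, j] - mu) / s
  }
  expect_lt(max(abs(z$values - oracle)), 1e-10)
})

test_that("time rescaling is the identity on the target axis", {
  target <- seq(-0.1, 1.1, length.out = 121)
  g <- tf_grid(0, 1); g$times <- target
  vals <- matrix(runif(121 * length(g$freqs)), 121)
  m <- tf_map(vals, g, "coherence")
  r <- rescale_time(m, onset = 0, offset = 1, n_bins = 121)
  expect_lt(max(abs(r$values - m$values)), 1e-12)
  expect_true(r$meta$rescaled)
})

test_that("rescaled maps share one shape and reproduce linear ramps", {
  g1 <- tf_grid(9, 21.2)     # event (10, 20), duration 10
  g2 <- tf_grid(27, 63.8)    # event (30, 60), duration 30
  f <- function(g) tf_map(matrix(g$times, length(g$times),
                                 length(g$freqs)), g, "power")
  r1 <- rescale_time(f(g1), 10, 20)
  r2 <- rescale_time(f(g2), 30, 60)
  expect_identical(dim(r1$values), dim(r2$values))
  # linear-in-time map: rescaled values equal the line at the target times
  expect_lt(max(abs(r1$values[, 1] - (10 + 10 * r1$times))), 1e-10)
  expect_lt(max(abs(r2$values[, 1] - (30 + 30 * r2$times))), 1e-10)
  expect_error(rescale_time(f(g1), 10, 40), "cover")
})

test_that("Gaussian smoothing preserves constants, mass and FWHM", {
  const <- make_rescaled_map(matrix(3, 121, 161))
  sm <- smooth_map(const)
  expect_lt(max(abs(sm$values - 3)), 1e-10)
  expect_error(smooth_map(const, fwhm_time_fraction = 0), "FWHM")

  imp <- matrix(0, 121, 161); imp[61, 81] <- 1
  m <- make_rescaled_map(imp)
  # narrow frequency kernel so its support is interior to the grid
  s <- smooth_map(m, fwhm_time_fraction = 0.05, fwhm_freq_hz = 1.5)
  expect_equal(sum(s$values), 1, tolerance = 1e-8)
  fwhm_t <- measure_fwhm(s$values[, 81], s$times)
  fwhm_f <- measure_fwhm(s$values[61, ], s$freqs)
  expect_equal(fwhm_t, 0.05, tolerance = 0.05)
  expect_equal(fwhm_f, 1.5, tolerance = 0.05)

  un <- tf_map(imp, tf_grid(0, 12), "power")
  expect_error(smooth_map(un), "rescaled")
})

test_that("smoothing is linear and positivity-preserving", {
  set.seed(11)
  a <- make_rescaled_map(matrix(rexp(121 * 161), 121))
  b <- make_rescaled_map(matrix(rexp(121 * 161), 121))
  sa <- smooth_map(a); sb <- smooth_map(b)
  ab <- a; ab$values <- a$values + b$values
  expect_equal(smooth_map(ab)$values, sa$values + sb$values,
               tolerance = 1e-12)
  expect_true(all(sa$values >= 0))
})

test_that("normalize and rescale commute on smooth maps", {
  g <- tf_grid(8, 22.4)          # event (10, 20)
  nt <- length(g$times); nf <- length(g$freqs)
  smooth_profile <- sin(2 * pi * g$times / 14) + 2
  vals <- outer(smooth_profile, seq(1, 3, length.out = nf))
  vals <- vals + outer(cos(g$times), rep(1, nf)) * 0.3
  m <- tf_map(vals, g, "power")

  a <- rescale_time(normalize_map(m, c(9, 10)), 10, 20)
  b <- normalize_map(rescale_time(m, 10, 20), c(-0.1, 0))
  expect_lt(max(abs(a$values - b$values)), 0.05)
})
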