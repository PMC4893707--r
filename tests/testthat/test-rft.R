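test_that("fixed-effects pooling stacks conditions and validates inputs", {
  mk <- function(animal, cond, val) {
    make_pooled_map(matrix(val + rnorm(1, sd = 1e-3), 12, 161), animal, cond)
  }
  maps <- c(lapply(1:4, function(a) mk(paste0("A", a), "pre", a)),
            lapply(1:4, function(a) mk(paste0("A", a), "post", a + 10)),
            lapply(1:4, function(a) mk(paste0("A", a), "pre", a + 20)),
            lapply(1:4, function(a) mk(paste0("A", a), "post", a + 30)))
  # 4 animals x 2 seizures per condition -> 8 + 8 observations
  pooled <- pool_fixed_effects(maps)
  expect_equal(pooled$n_pre, 8)
  expect_equal(pooled$n_post, 8)
  expect_equal(dim(pooled$pre)[3], 8)

  # an animal missing one condition is an error naming it
  bad <- maps[!(vapply(maps, function(m) m$meta$animal, "") == "A2" &
                  vapply(maps, function(m) m$meta$condition, "") == "post")]
  expect_error(pool_fixed_effects(bad), "A2")

  # duplicated map contents are flagged
  expect_warning(pool_fixed_effects(c(maps, maps[1])), "duplicated")

  # grid mismatch
  off_grid <- mk("A1", "pre", 1)
  off_grid$freqs <- off_grid$freqs + 0.05
  expect_error(pool_fixed_effects(c(maps, list(off_grid))), "common grid")
})

test_that("pixel-wise t-map matches hand-computed pooled-variance t", {
  pre <- array(0, c(1, 1, 3)); post <- array(0, c(1, 1, 3))
  pre[1, 1, ] <- c(1, 2, 3); post[1, 1, ] <- c(2, 4, 9)
  tm <- t_map(pre, post)
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(2, 4, 9))) / 4
  t_hand <- (2 - 5) / sqrt(sp2 * (2 / 3))
  expect_equal(tm$t[1, 1], t_hand, tolerance = 1e-10)
  expect_equal(tm$df, 4)

  # identical groups: t = 0 everywhere
  tm0 <- t_map(pre, pre)
  expect_true(all(tm0$t == 0))

  # one group constant: pooled variance still positive
  pre2 <- pre; pre2[1, 1, ] <- 2
  expect_true(is.finite(t_map(pre2, post)$t[1, 1]))

  expect_error(t_map(array(0, c(2, 2, 1)), post), "at least 2")
  # paired version
  tp <- t_map(pre, post, paired = TRUE)
  d <- c(1, 2, 3) - c(2, 4, 9)
  expect_equal(tp$t[1, 1], mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-10)
  expect_equal(tp$df, 2)
})

test_that("resel counts follow the rectangular-field formula", {
  expect_equal(unname(resel_counts(c(7, 11), 6, 10)), c(1, 2, 1))
  r <- resel_counts(c(121, 161), 1e9, 1e9)
  expect_lt(r[["R1"]] + r[["R2"]], 1e-6)
  expect_equal(resel_counts(c(121, 161), 6, 50)[["R2"]], 64)
  expect_error(resel_counts(c(10, 10), 0, 5), "FWHM")
})

test_that("RFT threshold reduces to the t quantile and is monotone", {
  expect_equal(rft_threshold(0.05, 30, c(1, 0, 0)), qt(0.95, 30),
               tolerance = 1e-6)
  u1 <- rft_threshold(0.05, 38, c(1, 10, 64))
  u2 <- rft_threshold(0.025, 38, c(1, 10, 64))
  expect_gt(u2, u1)
  # corrected threshold always exceeds the pointwise one
  expect_gt(u1, qt(0.95, 38))
  expect_error(rft_threshold(0, 38, c(1, 10, 64)), "alpha")
  expect_error(rft_threshold(0.05, 38, c(0, 0, 1e-12)), "no root")
})

test_that("thresholded null smooth t-fields keep the family-wise error", {
  set.seed(21)
  Tn <- 40; Fn <- 40; n <- 10
  fw_t <- 5; fw_f <- 8
  Wt <- swdmap:::gaussian_smoother(Tn, swdmap:::fwhm_to_sd(fw_t))
  Wf <- swdmap:::gaussian_smoother(Fn, swdmap:::fwhm_to_sd(fw_f))
  u <- rft_threshold(0.05, 2 * n - 2, resel_counts(c(Tn, Fn), fw_t, fw_f))
  reps <- 150
  hits <- 0
  for (r in seq_len(reps)) {
    pre <- array(0, c(Tn, Fn, n)); post <- array(0, c(Tn, Fn, n))
    for (i in seq_len(n)) {
      pre[, , i] <- Wt %*% matrix(rnorm(Tn * Fn), Tn) %*% t(Wf)
      post[, , i] <- Wt %*% matrix(rnorm(Tn * Fn), Tn) %*% t(Wf)
    }
    if (max(t_map(pre, post)$t) >= u) hits <- hits + 1
  }
  expect_lte(hits / reps, 0.05 + 2 * sqrt(0.05 * 0.95 / reps) + 0.02)
})

test_that("rft_inference assembles a coherent result object", {
  set.seed(22)
  maps <- c(lapply(1:6, function(i)
    make_pooled_map(matrix(rnorm(12 * 161), 12), "A1", "pre")),
    lapply(1:6, function(i)
      make_pooled_map(matrix(rnorm(12 * 161), 12), "A1", "post")))
  pooled <- pool_fixed_effects(maps)
  st <- rft_inference(pooled, fwhm_bins_t = 3, fwhm_bins_f = 30)
  expect_s3_class(st, "stat_result")
  expect_equal(st$df, 10)
  expect_identical(st$sig_mask, st$t_map >= st$u_star)
  two <- rft_inference(pooled, 3, 30, direction = "two.sided")
  expect_gt(two$u_star, st$u_star)
})
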