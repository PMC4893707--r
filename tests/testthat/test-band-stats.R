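test_that("central electrodes are the middle three of each row", {
  expect_setequal(central_electrodes(),
                  c("L2", "L3", "L4", "R2", "R3", "R4"))
  expect_setequal(adjacent_pairs(),
                  c("L1-L2", "L2-L3", "L3-L4", "L4-L5",
                    "R1-R2", "R2-R3", "R3-R4", "R4-R5"))
})

make_summary_map <- function(channel, animal, timepoint, value) {
  m <- make_rescaled_map(matrix(value, 121, 161), "power")
  m$kind <- "z-power"
  m$channel <- channel
  m$meta$animal <- animal
  m$meta$timepoint <- timepoint
  m
}

test_that("band summary averages band, ictal bins and electrodes", {
  maps <- list()
  for (a in c("A1", "A2")) for (tp in c("baseline", "1w"))
    for (ch in c("L2", "L3", "L4", "R2", "R3", "R4", "L1"))
      maps[[length(maps) + 1]] <-
        make_summary_map(ch, a, tp,
                         value = if (tp == "baseline") 4 else
                           if (startsWith(ch, "L")) 2 else 4)
  s <- band_summary(maps)
  expect_equal(nrow(s), 8)           # 2 animals x 2 timepoints x 2 sides
  expect_true(all(s$value[s$timepoint == "baseline"] == 4))
  expect_true(all(s$percent_baseline[s$timepoint == "baseline"] == 100))
  expect_equal(unique(s$percent_baseline[s$timepoint == "1w" &
                                         s$side == "left"]), 50)
  expect_equal(unique(s$percent_baseline[s$timepoint == "1w" &
                                         s$side == "right"]), 100)
  expect_error(band_summary(maps, band = c(1, 3)), "outside")
})

test_that("summary is invariant to electrode ordering", {
  set.seed(31)
  maps <- list()
  for (a in c("A1", "A2")) for (tp in c("baseline", "1w"))
    for (ch in c("L2", "L3", "L4", "R2", "R3", "R4"))
      maps[[length(maps) + 1]] <-
        make_summary_map(ch, a, tp, value = rnorm(1))
  s1 <- band_summary(maps)
  s2 <- band_summary(rev(maps))
  expect_equal(s1, s2)
})

toy_rows <- function(seed = 1, effect = 0) {
  set.seed(seed)
  d <- expand.grid(animal = paste0("A", 1:5),
                   timepoint = c("baseline", "1w", "3w", "9w"),
                   side = c("left", "right"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) +
    effect * (d$timepoint != "baseline") * (d$side == "left")
  d$percent_baseline <- d$value
  d
}

test_that("repeated-measures ANOVA matches the brute-force SS partition", {
  d <- toy_rows(2, effect = 1.5)
  an <- rm_anova_2way(d, dv = "value")
  # independent partition of the sums of squares
  y <- d$value; ybar <- mean(y)
  ssf <- function(f) {
    m <- tapply(y, f, mean)
    sum((m[f] - ybar)^2)
  }
  ss_t <- ssf(d$timepoint); ss_s <- ssf(d$side); ss_a <- ssf(d$animal)
  ss_ts <- ssf(interaction(d$timepoint, d$side)) - ss_t - ss_s
  ss_as <- ssf(interaction(d$animal, d$side)) - ss_a - ss_s
  ss_at <- ssf(interaction(d$animal, d$timepoint)) - ss_a - ss_t
  ss_within_resid <- sum((y - ybar)^2) -
    ss_a - ss_t - ss_s - ss_ts - ss_as - ss_at + ss_at
  f_time <- (ss_t / 3) / (ss_within_resid / 24)
  f_side <- (ss_s / 1) / (ss_as / 4)
  f_int <- (ss_ts / 3) / (ss_within_resid / 24)
  tab <- an$anova
  expect_equal(tab$F[tab$effect == "timepoint"], f_time, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "side"], f_side, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "timepoint:side"], f_int,
               tolerance = 1e-8)
})

test_that("degenerate and incomplete designs are handled", {
  d <- toy_rows(3)
  d$value <- 5; d$percent_baseline <- 5
  an <- rm_anova_2way(d, dv = "value")
  expect_true(all(an$anova$F == 0))
  expect_true(all(an$anova$p == 1))
  expect_true(all(an$posthoc$p_adj == 1))

  expect_error(rm_anova_2way(toy_rows(4)[-1, ], dv = "value"),
               "complete|missing")
})

test_that("post-hoc correction follows Bonferroni and Sidak", {
  d <- toy_rows(5, effect = 6)
  bon <- rm_anova_2way(d, dv = "value", posthoc = "bonferroni")
  sid <- rm_anova_2way(d, dv = "value", posthoc = "sidak")
  expect_equal(nrow(bon$posthoc), 6)  # 3 timepoints x 2 sides
  expect_equal(bon$posthoc$p_adj,
               pmin(1, bon$posthoc$p * 3), tolerance = 1e-12)
  expect_equal(sid$posthoc$p_adj,
               1 - (1 - sid$posthoc$p)^3, tolerance = 1e-12)
  # injected left-only effect shows up on the left side only
  expect_true(all(bon$posthoc$p_adj[bon$posthoc$side == "left"] < 0.05))
  expect_true(all(bon$posthoc$p_adj[bon$posthoc$side == "right"] > 0.05))
})

test_that("interictal band ANOVA flags only truly changed bands", {
  set.seed(32)
  bands <- c("delta", "theta", "alpha", "beta")
  pre <- matrix(rep(c(4, 3, 2, 1), each = 5) + rnorm(20, sd = 0.05),
                5, 4, dimnames = list(NULL, bands))
  ident <- interictal_band_stats(pre, pre)
  expect_true(all(ident$posthoc$p_adj == 1))

  post <- pre
  post[, "theta"] <- 2 * post[, "theta"] + rnorm(5, sd = 0.05)
  res <- interictal_band_stats(pre, post)
  expect_lt(res$posthoc$p_adj[res$posthoc$band == "theta"], 0.05)
  expect_true(all(res$posthoc$p_adj[res$posthoc$band != "theta"] > 0.05))

  expect_error(interictal_band_stats(pre[1, , drop = FALSE],
                                     post[1, , drop = FALSE]), "2 animals")
  colnames(post) <- c("delta", "theta", "alpha", "gamma")
  expect_error(interictal_band_stats(pre, post), "band sets differ")
})
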