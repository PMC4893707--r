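#' Band-level summaries and repeated-measures statistics
#'
#' Reduces normalized, rescaled maps to the 6-8 Hz band carried by the three
#' central electrodes of each hemisphere, expresses values as percent of each
#' animal's own baseline, and tests time-courses with a repeated-measures
#' two-way ANOVA (time x cortical side) plus per-timepoint post-hoc
#' comparisons against baseline.
#'
#' @name band-stats
NULL

#' Central electrodes of each hemisphere
#'
#' The three middle anteroposterior positions of each 5-electrode row.
#'
#' @param layout electrode table (see [default_layout()]).
#' @return character vector of channel labels.
#' @export
central_electrodes <- function(layout = default_layout()) {
  unlist(lapply(split(layout, layout$hemisphere), function(h) {
    h <- h[order(h$ap_mm, decreasing = TRUE), ]
    drop_n <- floor((nrow(h) - 3) / 2)
    h$label[(drop_n + 1):(drop_n + 3)]
  }), use.names = FALSE)
}

map_side <- function(channel, layout) {
  labs <- strsplit(as.character(channel), "-", fixed = TRUE)[[1]]
  sides <- unique(layout$hemisphere[match(labs, layout$label)])
  if (length(sides) != 1) NA_character_ else sides
}

#' Band summary rows from normalized maps
#'
#' For each map: mean z-value over the band frequencies and the ictal bins
#' (rescaled time in [0, 1]). Rows are then averaged over the selected
#' electrodes (channel pairs with both members selected, for coherence) to
#' one value per animal x timepoint x side x measure, and expressed as
#' percent of that animal/side/measure's baseline value.
#'
#' @param maps list of normalized, rescaled [tf_map()]s carrying
#'   `meta$animal`, `meta$timepoint` and (for pooling across conditions)
#'   the channel label or pair id in `$channel`.
#' @param band `c(lo, hi)` in Hz; must lie on the map grid.
#' @param electrodes channel labels to keep, or `"central-3"`.
#' @param layout electrode table used to resolve `"central-3"` and sides.
#' @param baseline_timepoint level treated as baseline.
#' @return data.frame with columns `animal`, `timepoint`, `side`, `measure`,
#'   `value`, `percent_baseline`.
#' @export
band_summary <- function(maps, band = c(6, 8), electrodes = "central-3",
                         layout = default_layout(),
                         baseline_timepoint = "baseline") {
  if (!length(maps)) stop("no maps", call. = FALSE)
  keep_labels <- if (identical(electrodes, "central-3"))
    central_electrodes(layout) else electrodes
  rows <- list()
  for (m in maps) {
    if (!isTRUE(m$meta$rescaled))
      stop("band_summary expects rescaled maps", call. = FALSE)
    if (band[1] < min(m$freqs) || band[2] > max(m$freqs))
      stop("band outside the map frequency grid", call. = FALSE)
    labs <- strsplit(as.character(m$channel), "-", fixed = TRUE)[[1]]
    if (!all(labs %in% keep_labels)) next
    side <- map_side(m$channel, layout)
    fsel <- m$freqs >= band[1] & m$freqs <= band[2]
    tsel <- m$times >= 0 & m$times <= 1
    rows[[length(rows) + 1L]] <- data.frame(
      animal = as.character(m$meta$animal),
      timepoint = as.character(m$meta$timepoint),
      side = side,
      measure = if (grepl("coherence", m$kind)) "coherence" else "power",
      value = mean(m$values[tsel, fsel]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no maps matched the electrode selection", call. = FALSE)
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ animal + timepoint + side + measure,
                          data = df, FUN = mean)
  base <- agg[agg$timepoint == baseline_timepoint,
              c("animal", "side", "measure", "value")]
  names(base)[4] <- "baseline_value"
  out <- merge(agg, base, by = c("animal", "side", "measure"))
  out$percent_baseline <- 100 * out$value / out$baseline_value
  out$baseline_value <- NULL
  out[order(out$measure, out$side, out$animal, out$timepoint),
      c("animal", "timepoint", "side", "measure", "value",
        "percent_baseline")]
}

## Extract one effect's row from a summary.aov stratum list.
aov_effect_row <- function(aov_summ, effect) {
  for (stratum in aov_summ) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    if (!is.na(i)) {
      resid <- match("Residuals", rn)
      return(data.frame(
        effect = effect,
        df1 = tab$Df[i],
        df2 = if (!is.na(resid)) tab$Df[resid] else NA_real_,
        F = tab$`F value`[i],
        p = tab$`Pr(>F)`[i],
        ss = tab$`Sum Sq`[i],
        ss_resid = if (!is.na(resid)) tab$`Sum Sq`[resid] else NA_real_))
    }
  }
  NULL
}

## Degenerate data (zero effect and residual SS) is reported as F = 0, p = 1.
clean_anova_table <- function(tab, tol = 1e-12) {
  degen <- (!is.finite(tab$F) | (tab$ss < tol & tab$ss_resid < tol)) &
    tab$ss < tol
  tab$F[degen] <- 0
  tab$p[degen] <- 1
  tab$ss <- NULL
  tab$ss_resid <- NULL
  tab
}

#' Repeated-measures two-way ANOVA on band summaries
#'
#' Fits `value ~ timepoint * side` with error strata `animal/side`
#' (cortical side is the within-animal factor; with the same animals present
#' at every timepoint the time effect is tested in the within-animal
#' stratum). Post-hoc: per side, each post-baseline timepoint against
#' baseline with paired t-tests, corrected over the post-baseline timepoints
#' (Bonferroni by default, Sidak optionally).
#'
#' @param rows data.frame as from [band_summary()] (one `measure` at a
#'   time); must be complete and balanced.
#' @param dv response column, `"percent_baseline"` or `"value"`.
#' @param posthoc `"bonferroni"` or `"sidak"`.
#' @param alpha significance level for the stars.
#' @param baseline_timepoint baseline level.
#' @return object of class `swd_anova`: `anova` (effect, df1, df2, F, p) and
#'   `posthoc` (side, timepoint, mean_diff, t, df, p, p_adj, sig).
#' @export
rm_anova_2way <- function(rows, dv = "percent_baseline",
                          posthoc = c("bonferroni", "sidak"),
                          alpha = 0.05, baseline_timepoint = "baseline") {
  posthoc <- match.arg(posthoc)
  if (length(unique(rows$measure %||% "x")) > 1)
    stop("run rm_anova_2way on one measure at a time", call. = FALSE)
  rows$animal <- factor(rows$animal)
  rows$timepoint <- factor(rows$timepoint)
  rows$side <- factor(rows$side)
  cells <- table(rows$animal, rows$timepoint, rows$side)
  if (any(cells != 1)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    lab <- apply(miss, 1, function(i)
      paste(dimnames(cells)[[1]][i[1]], dimnames(cells)[[2]][i[2]],
            dimnames(cells)[[3]][i[3]], sep = "/"))
    stop("design not complete/balanced; missing or duplicated cells: ",
         paste(utils::head(lab, 5), collapse = ", "), call. = FALSE)
  }
  rows$.y <- rows[[dv]]
  fit <- stats::aov(.y ~ timepoint * side + Error(animal / side),
                    data = rows)
  summ <- summary(fit)
  tab <- rbind(aov_effect_row(summ, "timepoint"),
               aov_effect_row(summ, "side"),
               aov_effect_row(summ, "timepoint:side"))
  tab <- clean_anova_table(tab)

  tps <- setdiff(levels(rows$timepoint), baseline_timepoint)
  n_cmp <- length(tps)
  ph <- list()
  for (s in levels(rows$side)) {
    base <- rows[rows$side == s & rows$timepoint == baseline_timepoint, ]
    base <- base[order(base$animal), ]
    for (tp in tps) {
      cur <- rows[rows$side == s & rows$timepoint == tp, ]
      cur <- cur[order(cur$animal), ]
      d <- cur$.y - base$.y
      if (stats::sd(d) == 0) {
        tstat <- 0; p <- 1
      } else {
        tt <- stats::t.test(d)
        tstat <- unname(tt$statistic); p <- tt$p.value
      }
      p_adj <- if (posthoc == "bonferroni") min(1, p * n_cmp)
               else 1 - (1 - p)^n_cmp
      ph[[length(ph) + 1L]] <- data.frame(
        side = s, timepoint = tp, mean_diff = mean(d),
        t = tstat, df = length(d) - 1, p = p, p_adj = p_adj,
        sig = if (p_adj < 0.01) "**" else if (p_adj < alpha) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(anova = tab, posthoc = do.call(rbind, ph),
                 dv = dv, posthoc_method = posthoc, alpha = alpha),
            class = "swd_anova")
}

#' @export
print.swd_anova <- function(x, ...) {
  cat("Repeated-measures two-way ANOVA (", x$dv, ")\n", sep = "")
  print(x$anova, row.names = FALSE, digits = 4)
  cat("Post-hoc vs baseline (", x$posthoc_method, "):\n", sep = "")
  print(x$posthoc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Interictal band amplitude statistics
#'
#' Two-way repeated-measures ANOVA of interictal FFT band amplitudes with
#' time (pre/post) and frequency band as factors, error strata
#' `animal/band`, plus per-band paired post-hoc comparisons corrected across
#' bands.
#'
#' @param pre,post numeric matrices, animals x bands (identical band
#'   columns, >= 2 animals), e.g. rows of [interictal_band_fft()] values
#'   averaged over epochs.
#' @param posthoc,alpha as in [rm_anova_2way()].
#' @return object of class `swd_anova` with per-band post-hoc rows.
#' @export
interictal_band_stats <- function(pre, post,
                                  posthoc = c("bonferroni", "sidak"),
                                  alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(colnames(pre), colnames(post)))
    stop("band sets differ between conditions", call. = FALSE)
  if (nrow(pre) != nrow(post))
    stop("conditions must have the same animals", call. = FALSE)
  if (nrow(pre) < 2)
    stop("need >= 2 animals (no within-subject variance otherwise)",
         call. = FALSE)
  bands <- colnames(pre)
  n_a <- nrow(pre)
  long <- data.frame(
    animal = factor(rep(seq_len(n_a), times = 2 * length(bands))),
    time = factor(rep(c("pre", "post"), each = n_a * length(bands)),
                  levels = c("pre", "post")),
    band = factor(rep(rep(bands, each = n_a), times = 2), levels = bands),
    value = c(as.vector(pre), as.vector(post)))
  fit <- stats::aov(value ~ time * band + Error(animal / band), data = long)
  summ <- summary(fit)
  tab <- rbind(aov_effect_row(summ, "time"),
               aov_effect_row(summ, "band"),
               aov_effect_row(summ, "time:band"))
  tab <- clean_anova_table(tab)
  ph <- lapply(bands, function(b) {
    d <- post[, b] - pre[, b]
    if (stats::sd(d) == 0) {
      tstat <- 0; p <- 1
    } else {
      tt <- stats::t.test(d)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    p_adj <- if (posthoc == "bonferroni") min(1, p * length(bands))
             else 1 - (1 - p)^length(bands)
    data.frame(band = b, mean_diff = mean(d), t = tstat, df = n_a - 1,
               p = p, p_adj = p_adj,
               sig = if (p_adj < 0.01) "**" else if (p_adj < alpha) "*"
                     else "",
               stringsAsFactors = FALSE)
  })
  structure(list(anova = tab, posthoc = do.call(rbind, ph),
                 dv = "band amplitude", posthoc_method = posthoc,
                 alpha = alpha),
            class = "swd_anova")
}
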