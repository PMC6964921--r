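# Directional hypothesis checks on an analysed dataset.
#
# H1: small |PE_pred| (within +/-5 deg at the step) produces longer and
#     more variable trigger times than large |PE_pred|.
# H2: the foveopetal 0 <= T_xt < 400 ms bin has the longest and most
#     variable trigger times of the three T_xt bins.
# H3: target blur lengthens trigger times, most strongly at small PE_pred.
# H4: larger |VS| (more signal-dependent noise) produces longer trigger
#     times at matched T_xt, and a lower saccade proportion at matched
#     PE_pred.

.pooled_bin_stats <- function(metrics, scheme, value_col = NULL,
                              condition = NULL) {
  d <- metrics
  if (!is.null(condition)) d <- d[d$condition == condition, , drop = FALSE]
  b <- bin_trials(d, scheme, value_col)
  sp <- split(b, b$bin, drop = FALSE)
  rows <- lapply(names(sp), function(nm) {
    d <- sp[[nm]]
    tt <- d$trigger_time[!is.na(d$trigger_time)]
    data.frame(bin = nm, n = nrow(d),
               median_trigger = if (length(tt)) stats::median(tt) else NA,
               iqr_trigger = if (length(tt) > 1) .iqr7(tt) else NA,
               prop_smooth = if (nrow(d)) mean(d$klass == "smooth") else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Directional hypothesis checks on a metrics table
#'
#' Evaluates the four directional predictions of the trigger model on
#' pooled trial metrics (see the package vignette). Each check compares
#' pooled medians/IQRs/smooth proportions across canonical bins.
#'
#' @param metrics Metrics data frame from [analyze_dataset()].
#' @return Data frame with hypothesis, check, value_a, value_b, pass.
#' @export
hypothesis_checks <- function(metrics) {
  sch <- canonical_bin_schemes()
  rows <- list()
  add <- function(h, check, a, b, pass)
    rows[[length(rows) + 1]] <<- data.frame(
      hypothesis = h, check = check, value_a = a, value_b = b,
      pass = isTRUE(pass), stringsAsFactors = FALSE)

  clear <- metrics[metrics$condition == "clear", , drop = FALSE]
  blur <- metrics[metrics$condition == "blur", , drop = FALSE]

  # H1: small vs large PE_pred (clear condition)
  s1 <- .pooled_bin_stats(clear, sch$pe_pred_coarse)
  small <- s1[s1$bin == "[-5,5)", ]
  large_med <- mean(s1$median_trigger[s1$bin != "[-5,5)"], na.rm = TRUE)
  large_iqr <- mean(s1$iqr_trigger[s1$bin != "[-5,5)"], na.rm = TRUE)
  add("H1", "median small > large PE_pred", small$median_trigger,
      large_med, small$median_trigger > large_med)
  add("H1", "IQR small > large PE_pred", small$iqr_trigger, large_iqr,
      small$iqr_trigger > large_iqr)

  # H2: T_xt bins (clear condition)
  s2 <- .pooled_bin_stats(clear, sch$txt)
  mid <- s2[s2$bin == "[0,400)", ]
  oth_med <- max(s2$median_trigger[s2$bin != "[0,400)"], na.rm = TRUE)
  oth_iqr <- max(s2$iqr_trigger[s2$bin != "[0,400)"], na.rm = TRUE)
  add("H2", "median highest in [0,400) T_xt", mid$median_trigger, oth_med,
      mid$median_trigger > oth_med)
  add("H2", "IQR highest in [0,400) T_xt", mid$iqr_trigger, oth_iqr,
      mid$iqr_trigger > oth_iqr)

  # H3: blur vs clear, overall and at small PE_pred
  sc <- .pooled_bin_stats(clear, sch$pe_pred_coarse)
  sb <- .pooled_bin_stats(blur, sch$pe_pred_coarse)
  mg <- merge(sc, sb, by = "bin", suffixes = c("_clear", "_blur"))
  diffs <- mg$median_trigger_blur - mg$median_trigger_clear
  d_small <- diffs[mg$bin == "[-5,5)"]
  d_large <- mean(diffs[mg$bin != "[-5,5)"], na.rm = TRUE)
  add("H3", "blur raises median trigger overall",
      mean(diffs, na.rm = TRUE), 0, mean(diffs, na.rm = TRUE) > 0)
  add("H3", "blur effect largest at small PE_pred", d_small, d_large,
      isTRUE(d_small > d_large))

  # H4: |VS| bands at matched T_xt (clear condition)
  b4 <- bin_trials(clear, sch$txt)
  b4$vs_band <- assign_bins(abs(b4$vs2), sch$vs_coarse)
  b4 <- b4[!is.na(b4$vs_band), , drop = FALSE]
  bands <- levels(b4$vs_band)
  lo <- b4[b4$vs_band == bands[1], ]
  hi <- b4[b4$vs_band == bands[length(bands)], ]
  med_by <- function(d) tapply(d$trigger_time, d$bin,
                               stats::median, na.rm = TRUE)
  dmed <- med_by(hi) - med_by(lo)
  add("H4", "higher |VS| lengthens trigger at matched T_xt",
      mean(dmed, na.rm = TRUE), 0,
      mean(dmed > 0, na.rm = TRUE) >= 0.5 && mean(dmed, na.rm = TRUE) > 0)
  # occurrence: at matched PE_pred (fine bins of the sampled value),
  # the high-|VS| band has the lower saccade proportion (SDN pattern)
  b9 <- bin_trials(clear, sch$pe_pred_fine, value_col = "pe_pred_sample")
  b9$vs_band <- assign_bins(abs(b9$vs2), sch$vs_coarse)
  b9 <- b9[!is.na(b9$vs_band), , drop = FALSE]
  pr <- function(d) tapply(d$klass != "smooth", d$bin, mean)
  cnt <- function(d) tapply(rep(1, nrow(d)), d$bin, sum)
  plo <- pr(b9[b9$vs_band == bands[1], ])
  phi <- pr(b9[b9$vs_band == bands[length(bands)], ])
  nlo <- cnt(b9[b9$vs_band == bands[1], ])
  nhi <- cnt(b9[b9$vs_band == bands[length(bands)], ])
  ok <- !is.na(plo) & !is.na(phi) & nlo >= 5 & nhi >= 5
  dprop <- (phi - plo)[ok]
  add("H4", "higher |VS| lowers saccade proportion at matched PE_pred",
      mean(dprop), 0,
      length(dprop) > 0 && mean(dprop <= 0) >= 0.5 && mean(dprop) < 0)

  do.call(rbind, rows)
}

#' Recover the extrapolation horizon from analysed trials
#'
#' Scans candidate horizons dt over the plausible 90-290 ms range,
#' recomputing |PE_pred(dt)| at the target step (from the step-window PE
#' and RS samples) for every non-excluded trial.
#'
#' Method `"occurrence"` (default) exploits the smooth zone: the zone is
#' the band PE_pred(dt) ~ 0, so the generating horizon is the one at
#' which |PE_pred(dt)| best separates saccade from smooth trials
#' (minimum logistic-regression deviance). Method `"trigger_variance"`
#' bins saccade trials into |PE_pred(dt)| quantile bins and minimises the
#' pooled within-bin variance of trigger times; its minimum is broader
#' because the accumulation dynamics weight slip slightly beyond the
#' extrapolation itself.
#'
#' @param metrics Metrics data frame with step-window samples.
#' @param grid Candidate horizons, ms.
#' @param method "occurrence" or "trigger_variance".
#' @param n_bins Quantile bins for the trigger-variance method.
#' @return List with `dt_ms` (best horizon), `method`, and the `scan`
#'   table (dt_ms, score).
#' @export
recover_extrapolation_horizon <- function(metrics,
                                          grid = seq(90, 290, by = 10),
                                          method = c("occurrence",
                                                     "trigger_variance"),
                                          n_bins = 10) {
  method <- match.arg(method)
  d <- metrics[!metrics$excluded & !is.na(metrics$pe_step), , drop = FALSE]
  if (method == "occurrence") {
    stopifnot(nrow(d) >= 50)
    sacc <- d$klass != "smooth"
    score <- vapply(grid, function(dt_ms) {
      pp <- abs(d$pe_step + dt_ms / 1000 * d$rs_step)
      suppressWarnings(
        stats::deviance(stats::glm(sacc ~ pp, family = stats::binomial)))
    }, numeric(1))
  } else {
    d <- d[!is.na(d$trigger_time), , drop = FALSE]
    stopifnot(nrow(d) >= 10 * n_bins)
    score <- vapply(grid, function(dt_ms) {
      pp <- abs(d$pe_step + dt_ms / 1000 * d$rs_step)
      qs <- unique(stats::quantile(pp, probs = seq(0, 1, length.out =
                                                     n_bins + 1)))
      b <- cut(pp, qs, include.lowest = TRUE)
      v <- tapply(d$trigger_time, b, stats::var)
      n <- tapply(d$trigger_time, b, length)
      sum(v * n, na.rm = TRUE) / sum(n[!is.na(v)])
    }, numeric(1))
  }
  list(dt_ms = grid[which.min(score)], method = method,
       scan = data.frame(dt_ms = grid, score = score))
}
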