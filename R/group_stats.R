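# Group statistics: bin schemes, per-subject medians/IQRs, saccade
# proportion curves, repeated-measures ANOVA with Bonferroni post-hocs and
# a BIC-approximated Bayes factor.
#
# Quartile convention: linear interpolation (stats::quantile type 7), so
# IQR({100,200,300}) = 100.

#' Define a binning scheme
#'
#' Edges are strictly increasing; bins are half-open [lo, hi). `bands`
#' defines a non-contiguous scheme (list of c(lo, hi) intervals) such as
#' the coarse |VS| bands; values between bands are unassigned (NA).
#'
#' @param variable One of "pe_pred", "txt", "txe", "vs_abs".
#' @param edges Numeric vector of increasing edges (may include +/-Inf).
#' @param bands Optional list of c(lo, hi) intervals instead of edges.
#' @return Object of class `bin_scheme`.
#' @export
bin_scheme <- function(variable, edges = NULL, bands = NULL) {
  variable <- match.arg(variable, c("pe_pred", "txt", "txe", "vs_abs"))
  if (is.null(bands)) {
    stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  } else {
    stopifnot(all(vapply(bands, length, 0L) == 2))
    lo <- vapply(bands, `[`, 0, 1)
    hi <- vapply(bands, `[`, 0, 2)
    stopifnot(all(hi > lo), all(lo[-1] >= hi[-length(hi)]))
  }
  structure(list(variable = variable, edges = edges, bands = bands),
            class = "bin_scheme")
}

#' Canonical bin schemes
#'
#' `pe_pred_coarse`: below -5, [-5, 5), 5 and above. `pe_pred_fine`: 2-deg
#' bins over [-20, 20]. `txt`: negative, [0, 400), 400 and above.
#' `txe`: 50-ms bins over [-400, 600]. `vs_abs5`: five 10-deg/s bands over
#' [0, 50]. `vs_coarse`: 0-10, 20-30, 40-50 deg/s bands.
#'
#' @return Named list of `bin_scheme` objects.
#' @export
canonical_bin_schemes <- function() {
  list(
    pe_pred_coarse = bin_scheme("pe_pred", c(-Inf, -5, 5, Inf)),
    pe_pred_fine = bin_scheme("pe_pred", seq(-20, 20, by = 2)),
    txt = bin_scheme("txt", c(-Inf, 0, 400, Inf)),
    txe = bin_scheme("txe", seq(-400, 600, by = 50)),
    vs_abs5 = bin_scheme("vs_abs", seq(0, 50, by = 10)),
    vs_coarse = bin_scheme("vs_abs",
                           bands = list(c(0, 10), c(20, 30), c(40, 50)))
  )
}

# default metrics column for each scheme variable
.scheme_column <- function(scheme) {
  switch(scheme$variable,
         pe_pred = "pe_pred_step", txt = "txt", txe = "txe_sample",
         vs_abs = "vs_abs")
}

#' Assign bin labels under a scheme
#'
#' @param x Numeric values.
#' @param scheme A `bin_scheme`.
#' @return Factor of bin labels ("[lo,hi)"); NA outside all bins.
#' @export
assign_bins <- function(x, scheme) {
  if (is.null(scheme$bands)) {
    e <- scheme$edges
    labs <- paste0("[", e[-length(e)], ",", e[-1], ")")
    i <- findInterval(x, e, left.open = FALSE, rightmost.closed = FALSE)
    i[i == 0 | i == length(e)] <- NA
    # values exactly at the top edge fall outside (half-open bins)
    i[!is.na(x) & x >= e[length(e)]] <- NA
    factor(labs[i], levels = labs)
  } else {
    labs <- vapply(scheme$bands, function(b)
      paste0("[", b[1], ",", b[2], ")"), "")
    out <- rep(NA_character_, length(x))
    for (k in seq_along(scheme$bands)) {
      b <- scheme$bands[[k]]
      out[!is.na(x) & x >= b[1] & x < b[2]] <- labs[k]
    }
    factor(out, levels = labs)
  }
}

#' Bin non-excluded trials under a scheme
#'
#' Every non-excluded trial with a defined value falls in exactly one bin.
#' Undefined values (NA, e.g. T_xe with near-zero slip) are dropped.
#'
#' @param metrics Metrics data frame from [analyze_dataset()].
#' @param scheme A `bin_scheme`.
#' @param value_col Metrics column to bin on; defaults by scheme variable
#'   (pe_pred -> pe_pred_step, txt -> txt, txe -> txe_sample, vs_abs ->
#'   |vs2|).
#' @return The metrics rows retained, with a `bin` factor column.
#' @export
bin_trials <- function(metrics, scheme, value_col = NULL) {
  stopifnot(inherits(scheme, "bin_scheme"))
  d <- metrics[!metrics$excluded, , drop = FALSE]
  if (is.null(value_col)) value_col <- .scheme_column(scheme)
  vals <- if (value_col == "vs_abs") abs(d$vs2) else d[[value_col]]
  d$bin <- assign_bins(vals, scheme)
  d[!is.na(d$bin), , drop = FALSE]
}

# linear-interpolation quartiles
.iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Per-subject, per-condition, per-bin summaries
#'
#' Median and IQR of trigger times (saccade trials only; linear
#' interpolation quartiles) and trial-type proportions. Bins with no
#' trials are omitted; bins with no saccade trials carry NA medians.
#'
#' @param binned Output of [bin_trials()].
#' @return Data frame with participant, condition, bin, n, n_saccade,
#'   median_trigger, iqr_trigger, prop_saccade, prop_early, prop_late,
#'   prop_smooth.
#' @export
summarize_bins <- function(binned) {
  sp <- split(binned,
              list(binned$participant, binned$condition, binned$bin),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    tt <- d$trigger_time[!is.na(d$trigger_time)]
    data.frame(
      participant = d$participant[1], condition = d$condition[1],
      bin = as.character(d$bin[1]), n = nrow(d), n_saccade = length(tt),
      median_trigger = if (length(tt)) stats::median(tt) else NA_real_,
      iqr_trigger = if (length(tt)) .iqr7(tt) else NA_real_,
      prop_saccade = mean(d$klass != "smooth"),
      prop_early = mean(d$klass == "early"),
      prop_late = mean(d$klass == "late"),
      prop_smooth = mean(d$klass == "smooth"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$condition, out$bin), , drop = FALSE]
}

#' Saccade-proportion curves over fine bins
#'
#' Fraction of saccade trials per bin of the sampled variable
#' (pre-saccadic sample for saccade trials, 400-ms post-step average for
#' smooth trials), optionally split by condition and |VS| band.
#'
#' @param metrics Metrics data frame.
#' @param scheme Fine `bin_scheme` (default 2-deg PE_pred bins), applied to
#'   the `*_sample` column.
#' @param by_condition Split curves by target condition?
#' @param vs_scheme Optional |VS| banding scheme for separate curves.
#' @return Data frame with bin, bin_mid, (condition, vs_band,) n,
#'   prop_saccade.
#' @export
proportion_curves <- function(metrics,
                              scheme = canonical_bin_schemes()$pe_pred_fine,
                              by_condition = TRUE, vs_scheme = NULL) {
  col <- switch(scheme$variable, pe_pred = "pe_pred_sample",
                txe = "txe_sample", .scheme_column(scheme))
  d <- bin_trials(metrics, scheme, value_col = col)
  keys <- list(bin = d$bin)
  if (by_condition) keys$condition <- d$condition
  if (!is.null(vs_scheme)) keys$vs_band <- assign_bins(abs(d$vs2), vs_scheme)
  agg <- stats::aggregate(d$klass != "smooth", by = keys,
                          FUN = function(z) c(n = length(z), p = mean(z)))
  out <- cbind(agg[setdiff(names(agg), "x")],
               n = agg$x[, "n"], prop_saccade = agg$x[, "p"])
  if (is.null(scheme$bands)) {
    e <- scheme$edges
    mids <- (e[-1] + e[-length(e)]) / 2
    out$bin_mid <- mids[as.integer(factor(out$bin,
                                          levels = levels(d$bin)))]
  }
  out
}

#' Repeated-measures ANOVA on per-subject cell values
#'
#' One- or two-way within-subject ANOVA via `stats::aov` with an
#' `Error(subject/...)` stratum. Duplicate rows per subject x cell are
#' averaged; subjects missing any cell are dropped listwise. Partial
#' eta-squared is SS_effect / (SS_effect + SS_error).
#'
#' @param data Data frame of per-subject cell values (e.g. from
#'   [summarize_bins()]).
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Subject identifier column.
#' @return Object of class `rm_anova`: list with `table` (effect, df1,
#'   df2, F, p, partial_eta_sq, ss_effect, ss_error), the cell `data`, and
#'   the design descriptors.
#' @export
rm_anova <- function(data, dv, within, subject = "participant") {
  stopifnot(length(within) %in% 1:2,
            all(c(dv, within, subject) %in% names(data)))
  d <- data[stats::complete.cases(data[c(dv, within, subject)]), ,
            drop = FALSE]
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  # average duplicates, then drop subjects with incomplete cells
  d <- stats::aggregate(d[dv], by = d[c(subject, within)], FUN = mean)
  cells <- interaction(d[within], drop = FALSE)
  full <- nlevels(cells)
  cnt <- tapply(cells, d[[subject]], function(z) length(unique(z)))
  keep <- names(cnt)[!is.na(cnt) & cnt == full]
  if (length(keep) < 2)
    stop("rm_anova: fewer than 2 subjects with complete cells")
  d <- d[d[[subject]] %in% keep, , drop = FALSE]
  d[[subject]] <- droplevels(d[[subject]])

  rhs <- paste(within, collapse = " * ")
  f <- stats::as.formula(
    paste(dv, "~", rhs, "+ Error(", subject, "/(", rhs, "))"))
  fit <- stats::aov(f, data = d)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    res <- which(terms == "Residuals")
    if (length(res) == 0) next
    for (k in seq_len(nrow(tab))) {
      if (terms[k] == "Residuals") next
      ss_e <- tab[k, "Sum Sq"]
      ss_r <- tab[res, "Sum Sq"]
      fval <- if (ss_e < 1e-12) 0 else tab[k, "F value"]
      pval <- if (ss_e < 1e-12) 1 else tab[k, "Pr(>F)"]
      rows[[length(rows) + 1]] <- data.frame(
        effect = terms[k], df1 = tab[k, "Df"], df2 = tab[res, "Df"],
        F = fval, p = pval,
        partial_eta_sq = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0,
        ss_effect = ss_e, ss_error = ss_r, stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), data = d, dv = dv,
                 within = within, subject = subject),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA on", x$dv, "(", nlevels(x$data[[x$subject]]),
      "subjects )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pairwise paired post-hoc comparisons
#'
#' All pairwise paired t tests between levels of a within-subject factor,
#' with Bonferroni correction (p multiplied by the number of comparisons,
#' capped at 1). Identical pairs (all differences zero) report p = 1.
#'
#' @param data Per-subject cell values (duplicates averaged).
#' @param dv Dependent-variable column.
#' @param within Single within-subject factor column.
#' @param subject Subject column.
#' @param correction Only "bonferroni" is implemented.
#' @return Data frame with level1, level2, n, mean_diff, t, df, p, p_adj.
#' @export
posthoc_paired <- function(data, dv, within, subject = "participant",
                           correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  d <- data[stats::complete.cases(data[c(dv, within, subject)]), ,
            drop = FALSE]
  d <- stats::aggregate(d[dv], by = d[c(subject, within)], FUN = mean)
  levs <- levels(factor(d[[within]]))
  prs <- utils::combn(levs, 2)
  m <- ncol(prs)
  rows <- lapply(seq_len(m), function(k) {
    a <- d[d[[within]] == prs[1, k], c(subject, dv)]
    b <- d[d[[within]] == prs[2, k], c(subject, dv)]
    mg <- merge(a, b, by = subject)
    diffs <- mg[[paste0(dv, ".x")]] - mg[[paste0(dv, ".y")]]
    n <- length(diffs)
    if (n < 2 || stats::sd(diffs) < 1e-12) {
      p <- if (n >= 1 && max(abs(diffs)) < 1e-12) 1 else 0
      return(data.frame(level1 = prs[1, k], level2 = prs[2, k], n = n,
                        mean_diff = mean(diffs), t = NA_real_,
                        df = n - 1, p = p, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(diffs)
    data.frame(level1 = prs[1, k], level2 = prs[2, k], n = n,
               mean_diff = mean(diffs), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' BIC Bayes-factor comparison of two fitted models
#'
#' BF10 = exp((BIC0 - BIC1) / 2): evidence for model 1 over model 0 under
#' the unit-information-prior approximation. A model compared with itself
#' gives 1.
#'
#' @param fit0,fit1 Fitted models accepted by [stats::BIC()].
#' @return BF10 (numeric).
#' @export
bic_bayes_factor <- function(fit0, fit1) {
  exp((stats::BIC(fit0) - stats::BIC(fit1)) / 2)
}

#' Approximate Bayes factor for a within-subject design
#'
#' Compares a linear model with the within-subject factors (plus subject
#' blocking) against the subject-only null via the BIC approximation.
#' This approximates the weight of evidence for any effect of the
#' within-subject factors; it is not a replication of any particular
#' Bayesian ANOVA implementation.
#'
#' @param data Per-subject cell values.
#' @param dv,within,subject As in [rm_anova()].
#' @return BF10 (numeric).
#' @export
bayes_factor_anova <- function(data, dv, within, subject = "participant") {
  d <- data[stats::complete.cases(data[c(dv, within, subject)]), ,
            drop = FALSE]
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  d <- stats::aggregate(d[dv], by = d[c(subject, within)], FUN = mean)
  f0 <- stats::as.formula(paste(dv, "~", subject))
  f1 <- stats::as.formula(paste(dv, "~", subject, "+",
                                paste(within, collapse = " * ")))
  bic_bayes_factor(stats::lm(f0, data = d), stats::lm(f1, data = d))
}
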