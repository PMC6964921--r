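# Binning, per-subject summaries, repeated-measures ANOVA, post-hocs,
# Bayes factors.

make_metrics <- function(pe_pred, trigger, subject = 1,
                         condition = "clear", klass = NULL, vs2 = 20) {
  n <- length(pe_pred)
  if (is.null(klass))
    klass <- ifelse(is.na(trigger), "smooth",
                    ifelse(trigger < 175, "early", "late"))
  data.frame(participant = rep_len(subject, n),
             condition = rep_len(condition, n),
             pe_pred_step = pe_pred, pe_pred_sample = pe_pred,
             trigger_time = trigger, klass = klass,
             vs2 = rep_len(vs2, n), txt = NA_real_,
             txe_sample = NA_real_, excluded = FALSE,
             stringsAsFactors = FALSE)
}

test_that("half-open bin edges assign boundary values upward", {
  sch <- canonical_bin_schemes()$pe_pred_coarse
  expect_equal(as.character(assign_bins(5.0, sch)), "[5,Inf)")
  expect_equal(as.character(assign_bins(-5.0, sch)), "[-5,5)")
  expect_equal(as.character(assign_bins(4.999, sch)), "[-5,5)")
  fine <- canonical_bin_schemes()$pe_pred_fine
  expect_true(is.na(assign_bins(20, fine)))   # top edge falls outside
  expect_equal(as.character(assign_bins(-20, fine)), "[-20,-18)")
})

test_that("every non-excluded trial lands in exactly one bin", {
  set.seed(70)
  m <- make_metrics(runif(500, -19.9, 19.9), runif(500, 100, 350))
  fine <- canonical_bin_schemes()$pe_pred_fine
  b <- bin_trials(m, fine)
  expect_equal(nrow(b), 500)
  expect_equal(sum(table(b$bin)), 500)
  # near-uniform values spread evenly over 2-degree bins
  chi <- chisq.test(table(b$bin))
  expect_gt(chi$p.value, 0.01)
})

test_that("banded schemes leave between-band values unassigned", {
  vs <- canonical_bin_schemes()$vs_coarse
  expect_equal(as.character(assign_bins(5, vs)), "[0,10)")
  expect_true(is.na(assign_bins(15, vs)))
  expect_equal(as.character(assign_bins(45, vs)), "[40,50)")
})

test_that("bin summaries use linear-interpolation quartiles", {
  m <- make_metrics(rep(0, 3), c(100, 200, 300))
  s <- summarize_bins(bin_trials(m, canonical_bin_schemes()$pe_pred_coarse))
  expect_equal(s$median_trigger, 200)
  expect_equal(s$iqr_trigger, 100)
  expect_equal(s$prop_saccade, 1)
  # all-smooth bin: missing median, prop_smooth 1
  m2 <- make_metrics(rep(0, 4), rep(NA_real_, 4))
  s2 <- summarize_bins(bin_trials(m2, canonical_bin_schemes()$pe_pred_coarse))
  expect_true(is.na(s2$median_trigger))
  expect_equal(s2$prop_smooth, 1)
})

test_that("per-bin medians are recovered exactly from a scripted table", {
  set.seed(71)
  vals <- list("a" = c(150, 210, 250), "b" = c(300, 340, 420))
  m <- rbind(make_metrics(rep(-10, 3), vals$a),
             make_metrics(rep(10, 3), vals$b))
  s <- summarize_bins(bin_trials(m, canonical_bin_schemes()$pe_pred_coarse))
  expect_equal(s$median_trigger[s$bin == "[-Inf,-5)"], 210)
  expect_equal(s$median_trigger[s$bin == "[5,Inf)"], 340)
})

test_that("proportion curves saturate when every trial saccades", {
  m <- make_metrics(runif(200, -10, 10), runif(200, 100, 390))
  pc <- proportion_curves(m, by_condition = FALSE)
  expect_true(all(pc$prop_saccade == 1))
})

test_that("one-way repeated-measures ANOVA matches the paired t identity", {
  set.seed(72)
  n <- 12
  d <- data.frame(participant = rep(1:n, 2),
                  bin = rep(c("A", "B"), each = n),
                  y = c(rnorm(n, 10), rnorm(n, 12)))
  fit <- rm_anova(d, "y", "bin")
  tt <- t.test(d$y[d$bin == "A"] - d$y[d$bin == "B"])
  expect_equal(fit$table$F, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(fit$table$p, tt$p.value, tolerance = 1e-6)
  expect_equal(fit$table$df1, 1)
  expect_equal(fit$table$df2, n - 1)
})

test_that("identical cell values give a zero F", {
  d <- expand.grid(participant = 1:6, bin = c("A", "B", "C"))
  d$y <- 5
  fit <- rm_anova(d, "y", "bin")
  expect_equal(fit$table$F, 0)
  expect_equal(fit$table$p, 1)
})

test_that("two-way repeated-measures ANOVA reports the interaction", {
  set.seed(73)
  d <- expand.grid(participant = 1:10, bin = c("A", "B", "C"),
                   condition = c("clear", "blur"))
  d$y <- rnorm(nrow(d)) + ifelse(d$bin == "B" & d$condition == "blur", 3, 0)
  fit <- rm_anova(d, "y", c("bin", "condition"))
  expect_setequal(fit$table$effect, c("bin", "condition", "bin:condition"))
  inter <- fit$table[fit$table$effect == "bin:condition", ]
  expect_lt(inter$p, 0.01)
  expect_true(all(fit$table$partial_eta_sq >= 0 &
                    fit$table$partial_eta_sq <= 1))
})

test_that("subjects with incomplete cells are dropped listwise", {
  d <- expand.grid(participant = 1:5, bin = c("A", "B", "C"))
  d$y <- rnorm(nrow(d))
  d <- d[!(d$participant == 5 & d$bin == "C"), ]
  fit <- rm_anova(d, "y", "bin")
  expect_equal(nlevels(fit$data$participant), 4)
  expect_error(rm_anova(d[d$participant == 1, ], "y", "bin"),
               "fewer than 2")
})

test_that("Bonferroni post-hocs count and cap correctly", {
  set.seed(74)
  d <- expand.grid(participant = 1:10, bin = c("A", "B", "C"))
  d$y <- rnorm(nrow(d))
  ph <- posthoc_paired(d, "y", "bin")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adj <= 1))
  expect_true(all(ph$p_adj >= pmin(1, ph$p * 3) - 1e-12))
  # identical pair: p = 1 after capping
  d2 <- d; d2$y[d2$bin == "B"] <- d2$y[d2$bin == "A"]
  ph2 <- posthoc_paired(d2, "y", "bin")
  ab <- ph2[ph2$level1 == "A" & ph2$level2 == "B", ]
  expect_equal(ab$p_adj, 1)
})

test_that("post-hocs detect a shifted bin and spare the null pair", {
  set.seed(75)
  hits_shift <- 0; hits_null <- 0; reps <- 150
  for (r in 1:reps) {
    d <- expand.grid(participant = 1:15, bin = c("A", "B", "C"))
    d$y <- rnorm(nrow(d)) + ifelse(d$bin == "C", 2, 0)   # 2-SD shift
    ph <- posthoc_paired(d, "y", "bin")
    sig <- ph$p_adj < 0.05
    involved <- ph$level1 == "C" | ph$level2 == "C"
    if (all(sig[involved])) hits_shift <- hits_shift + 1
    if (any(sig[!involved])) hits_null <- hits_null + 1
  }
  expect_gte(hits_shift / reps, 0.95)
  expect_lte(hits_null / reps, 0.10)
})

test_that("BIC Bayes factors separate null from strong effects", {
  set.seed(76)
  bf_null <- bf_eff <- numeric(100)
  for (r in 1:100) {
    d <- expand.grid(participant = 1:15, bin = c("A", "B", "C"))
    d$y0 <- rnorm(nrow(d))
    d$y1 <- d$y0 + ifelse(d$bin == "C", 2, 0)
    bf_null[r] <- bayes_factor_anova(d, "y0", "bin")
    bf_eff[r] <- bayes_factor_anova(d, "y1", "bin")
  }
  expect_gt(mean(bf_null < 1), 0.5)
  expect_gte(mean(bf_eff > 10), 0.95)
  # a model against itself is even evidence
  fit <- lm(y0 ~ bin, data = expand.grid(participant = 1:5,
                                         bin = c("A", "B"), y0 = 1))
  expect_equal(bic_bayes_factor(fit, fit), 1)
})
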