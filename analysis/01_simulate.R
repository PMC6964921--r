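#!/usr/bin/env Rscript
# Stage 1: simulate a model-mode dataset of double step-ramp trials.
#
# Five simulated observers each complete two sessions (one clear, one
# blurred target) of four 50-trial blocks -- 2000 trials, enough for the
# binned group statistics and the band-resolved proportion curves while
# staying desk-sized. Traces are written under scratch/ (regenerable;
# not a deliverable), the manifest summary under results/.

library(catchup)

cfg <- merge_config(default_config(), list(
  seed = 20240901L,
  schedule = list(n_participants = 5, sessions = 2, blocks = 4,
                  trials_per_block = 50)
))

dir.create("results", showWarnings = FALSE)
ds <- run_simulate(cfg, mode = "model", out_dir = "scratch/dataset")

n_cond <- table(ds$truth$condition)
cat("simulated", length(ds$traces), "trials:",
    n_cond[["clear"]], "clear /", n_cond[["blur"]], "blurred\n")
cat("ground-truth saccade trials:",
    sum(!is.na(ds$truth$trigger_ms)), "\n")
write.csv(ds$truth, "scratch/simulated_truth.csv", row.names = FALSE)
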