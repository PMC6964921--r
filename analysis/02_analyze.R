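#!/usr/bin/env Rscript
# Stage 2: run the per-trial analysis chain on the simulated dataset.
#
# Zero-phase 50-Hz filtering, central-difference kinematics, 750 deg/s^2
# saccade detection, exclusion rules, and the PE_pred / T_xe / T_xt
# metrics. One metrics row per trial lands in scratch/metrics.csv; the
# exclusion tally in results/exclusions.csv.

library(catchup)

cfg <- merge_config(default_config(), list(seed = 20240901L))
metrics <- run_analyze("scratch/dataset", cfg,
                       out_file = "scratch/metrics.csv")

excl <- exclusion_report(metrics)
write.csv(excl, "results/exclusions.csv", row.names = FALSE)

cat("analysed", nrow(metrics), "trials;",
    sum(metrics$excluded), "excluded (",
    round(100 * mean(metrics$excluded), 1), "% )\n")
print(excl)
kept <- metrics[!metrics$excluded, ]
print(table(kept$condition, kept$klass))
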