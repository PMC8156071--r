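#!/usr/bin/env Rscript
# Stage 5 — quality-controlled evaluation.
#
# Aggregates tumor-free origins into one reference class, applies the
# patch-level (PQC) and case-level (CQC) quality-control thresholds over
# the 5 x 5 grid, and reports balanced accuracy with the two rejection
# percentages, plus patch- and case-level confusion matrices without QC.

library(lymphopatch)
cfg <- load_pipeline_config(file.path("analysis", "pipeline.yaml"))

run_pipeline(cfg, stages = "qc_grid")

wide <- read.csv(file.path(cfg$workdir, "qc_grid", "grid_wide.csv"))
cat("Balanced accuracy (%) per PQC row and CQC column:\n")
print(wide[, c("pqc_pct", "pqc_not_met",
               grep("^bacc", names(wide), value = TRUE))])
long <- read.csv(file.path(cfg$workdir, "qc_grid", "grid_long.csv"))
top <- long[which.max(long$bacc_pct), ]
cat(sprintf("Best cell: BACC %.2f%% at PQC %.0f%% / CQC %.0f%% (%.1f%% of cases abstained)\n",
            top$bacc_pct, 100 * top$pqc, 100 * top$cqc,
            top$cqc_not_met_pct))
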