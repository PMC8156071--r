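#!/usr/bin/env Rscript
# Stage 4 — learning-rate screening and training.
#
# Screens the candidate learning rates for a few epochs from a shared
# initialization, trains the chosen one further with early stopping, and
# writes per-epoch accuracy curves plus per-patch class-probability tables
# for the validation and test sets.

library(lymphopatch)
cfg <- load_pipeline_config(file.path("analysis", "pipeline.yaml"))

run_pipeline(cfg, stages = "train")

curves <- read.csv(file.path(cfg$workdir, "train", "curves.csv"))
best <- which.max(curves$val_acc)
cat(sprintf(paste0("Trained %d epochs; best validation accuracy %.1f%% at",
                   " epoch %d (overfit gap %.1f pp)\n"),
            nrow(curves), 100 * curves$val_acc[best], curves$epoch[best],
            100 * curves$overfit_gap[best]))
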