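#!/usr/bin/env Rscript
# Stage 3 — patient-level subset assignment.
#
# Splits patients 60/20/20 into training/validation/test, stratified by
# class; all patches of a patient follow the patient. The leak checkpoint
# runs again at training time.

library(lymphopatch)
cfg <- load_pipeline_config(file.path("analysis", "pipeline.yaml"))

run_pipeline(cfg, stages = "split")

cat(readLines(file.path(cfg$workdir, "split", "subset_summary.txt")),
    sep = "\n")
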