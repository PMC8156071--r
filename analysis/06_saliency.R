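#!/usr/bin/env Rscript
# Stage 6 — SmoothGrad explanations.
#
# Computes SmoothGrad heatmaps (noise 0.5%, 50 samples) for one example
# patch per class and writes grayscale heatmaps, overlays and JSON
# provenance sidecars.

library(lymphopatch)
cfg <- load_pipeline_config(file.path("analysis", "pipeline.yaml"))

run_pipeline(cfg, stages = "saliency")

files <- list.files(file.path(cfg$workdir, "saliency"), pattern = "png$")
cat("Saliency outputs:\n")
cat(paste(" ", files), sep = "\n")
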