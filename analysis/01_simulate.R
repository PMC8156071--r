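#!/usr/bin/env Rscript
# Stage 1 — simulate the annotated cohort.
#
# Renders one H&E-like tissue image per synthetic patient, with a
# class-labeled polygon annotation and a cohort manifest, standing in for
# a scanned, pathologist-annotated tissue microarray.

library(lymphopatch)
cfg <- load_pipeline_config(file.path("analysis", "pipeline.yaml"))

run_pipeline(cfg, stages = "synth")

man <- read.csv(file.path(cfg$workdir, "synth", "manifest.csv"))
cat(sprintf("Simulated %d cases across %d classes -> %s\n",
            nrow(man), length(unique(man$class)),
            file.path(cfg$workdir, "synth")))
print(table(man$class))
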