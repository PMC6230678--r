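#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 18 controls, 13 EoE without food
# impaction, 14 EoE with food impaction, profiled on the 74-gene panel with
# 5 housekeepers and spike-in controls. Writes per-lane RCC files, the
# combined count matrix, the clinical metadata, and the ground truth.

suppressPackageStartupMessages(library(fiscope))
suppressPackageStartupMessages(library(jsonlite))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20181105)
sim <- simulate_counts(cfg)
meta <- simulate_metadata(cfg)

write_rcc(sim$counts, file.path(out, "rcc"))
write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write_probe_annotation(sim$counts$annotation, file.path(out, "probes.tsv"))
write_clinical_table(meta, file.path(out, "metadata.tsv"))
write_json(sim$truth, file.path(out, "truth.json"), auto_unbox = TRUE,
           digits = NA)

cat("Cohort:", ncol(sim$counts$counts), "lanes x",
    nrow(sim$counts$counts), "probes\n")
print(table(meta$group))
cat("Planted FI-specific fold changes (EoE+FI vs EoE no FI):\n")
print(cfg$fi_effect)
cat("Outputs under", out, "\n")
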