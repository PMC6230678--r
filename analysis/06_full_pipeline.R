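#!/usr/bin/env Rscript
# End-to-end diagnostic run: normalization, the primary EoE probability
# gate (pluggable default model), differential expression, the FI scoring
# loop with its ROC-derived cutoff, and per-sample loop decisions, written
# as a versioned machine-readable report.

suppressPackageStartupMessages(library(fiscope))

raw <- read_rcc_dir("results/cohort/rcc")
meta <- read_clinical_table("results/cohort/metadata.tsv")

res <- run_pipeline(raw, meta, config = list(gate = list(enabled = TRUE)))
write_report(res, "results/pipeline")

d <- res$decisions
cat("Decisions for", nrow(d), "samples -> results/pipeline/\n")
cat("EoE gate (p(EoE) > 25) by true group:\n")
print(table(gate = d$eoe_gate, group = d$group))
eoe <- d$group != "Control"
cat(sprintf("FI calls among EoE: %d/%d called, true FI detected %d/%d\n",
            sum(d$fi_call[eoe]), sum(eoe),
            sum(d$fi_call[eoe] & d$group[eoe] == "EoE_FI"),
            sum(d$group == "EoE_FI")))
cat(sprintf("FI-score AUC %.3f at cutoff %.3f\n",
            res$fi$roc$auc, res$fi$cutoff))
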