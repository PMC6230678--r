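#!/usr/bin/env Rscript
# Normalize the simulated cohort from its RCC lane files: background
# subtraction (mean of negatives), scaling to the geometric mean of the
# positive controls, then to the geometric mean of the 5 housekeepers.

suppressPackageStartupMessages(library(fiscope))

raw <- read_rcc_dir("results/cohort/rcc")
norm <- normalize_lanes(raw)

df <- data.frame(gene = rownames(norm$values), norm$values,
                 check.names = FALSE)
write.table(df, "results/normalized.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
qc <- data.frame(lane = colnames(norm$values),
                 background = norm$background,
                 pos_factor = norm$pos_factor,
                 hk_factor = norm$hk_factor,
                 flagged = lengths(norm$qc_flags) > 0)
write.table(qc, "results/normalization_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Normalized", nrow(norm$values), "endogenous genes x",
    ncol(norm$values), "lanes\n")
cat(sprintf("Scale factors: positives %.2f-%.2f, housekeeping %.2f-%.2f\n",
            min(norm$pos_factor), max(norm$pos_factor),
            min(norm$hk_factor), max(norm$hk_factor)))
cat(sum(lengths(norm$qc_flags) > 0), "lane(s) flagged,",
    length(norm$excluded), "excluded\n")
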