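#!/usr/bin/env Rscript
# Composite FI-score: transcript weights (fold difference x adjusted
# significance, L1-normalized), weighted one-factor projection of per-gene
# standardized expression over the EoE cohort, standardization, ROC-derived
# cutoff, and calls. Also reports the leave-one-out check.

suppressPackageStartupMessages(library(fiscope))
suppressPackageStartupMessages(library(jsonlite))

norm_df <- read.delim("results/normalized.tsv", check.names = FALSE)
meta <- read_clinical_table("results/cohort/metadata.tsv")
values <- as.matrix(norm_df[, -1])
rownames(values) <- norm_df$gene
norm <- structure(list(values = values), class = "normalized_matrix")
grp <- factor(meta$group[match(colnames(values), meta$sample_id)],
              levels = c("Control", "EoE_no_FI", "EoE_FI"))

fi <- fi_signature(norm, grp)
w <- fi$weights$weights[fi$weights$weights != 0]
write.table(data.frame(gene = names(w), weight = w),
            "results/fi_weights.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
scores <- data.frame(sample_id = names(fi$standardized),
                     group = as.character(grp[match(names(fi$standardized),
                                                    meta$sample_id)]),
                     raw = fi$raw, standardized = fi$standardized,
                     call = fi$calls)
write.table(scores, "results/fi_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

loo <- loo_fi_scores(norm, grp)
cmx <- fi$roc$at_cutoff
write_json(list(auc = fi$roc$auc, se = fi$roc$se, cutoff = fi$cutoff,
                sensitivity = cmx$sensitivity, specificity = cmx$specificity,
                ppv = cmx$ppv, npv = cmx$npv, loo_auc = loo$auc),
           "results/fi_roc.json", auto_unbox = TRUE, digits = NA)

cat("Signature size:", length(w), "transcripts, all negative:",
    all(w < 0), "\n")
cat(sprintf("In-sample AUC %.3f (Hanley-McNeil SE %.3f), LOO AUC %.3f\n",
            fi$roc$auc, fi$roc$se, loo$auc))
cat(sprintf("Youden cutoff %.3f: sensitivity %.3f, specificity %.3f, PPV %.3f, NPV %.3f\n",
            fi$cutoff, cmx$sensitivity, cmx$specificity, cmx$ppv, cmx$npv))
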