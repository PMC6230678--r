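#' Default targeted esophageal mRNA panel
#'
#' A stand-in for the targeted EoE-transcriptome panel: 74 endogenous probes
#' (the named marker genes profiled in the study plus stable placeholder
#' probes `GENE_009` ... so fixtures reproduce byte-for-byte), 5 housekeeping
#' probes, 6 positive spike-in controls on a 4-fold concentration ladder
#' (128 down to 0.125 fM, the platform-standard ERCC ladder), and 8 negative
#' controls. Real panel definitions can be supplied instead via
#' [read_probe_annotation()].
#'
#' Named endogenous genes: mast-cell markers (`CPA3`, `FCER1B`), the mast-cell
#' precursor chemokine `CCL2`, the eosinotrophic chemokine `CCL26`, Th2
#' cytokines (`IL4`, `IL5`, `IL13`), and the motility regulators `NOS2` and
#' `HIF1A`.
#'
#' @return A [probe_annotation()] with 93 probes.
#' @export
default_panel <- function() {
  named <- c("CPA3", "FCER1B", "CCL2", "CCL26", "IL4", "IL5", "IL13",
             "NOS2", "HIF1A")
  n_placeholder <- 74 - length(named)
  endo <- c(named, sprintf("GENE_%03d", seq_len(n_placeholder) + length(named)))
  hk <- c("ACTB", "GAPDH", "RPL19", "TBP", "HPRT1")
  pos <- sprintf("POS_%s(%g)", LETTERS[1:6], 128 / 4^(0:5))
  neg <- sprintf("NEG_%s", LETTERS[1:8])
  probe_annotation(
    probe = c(endo, hk, pos, neg),
    class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                times = c(74L, 5L, 6L, 8L)),
    accession = sprintf("NM_%06d.1", seq_len(74 + 5 + 6 + 8)),
    concentration = c(rep(NA_real_, 74 + 5), 128 / 4^(0:5), rep(NA_real_, 8))
  )
}

#' Default planted expression effects
#'
#' `default_eoe_effect()` returns the fold changes applied to both EoE groups
#' relative to controls (the EoE-wide inflammatory up-regulation the panel
#' was designed around — strong for the eosinophil-axis transcripts `CCL26`
#' and `IL13`, modest for the mast-cell/Th2 markers, so that the FI-specific
#' down-regulation leaves the FI group at or below control levels for those
#' markers, consistent with their non-elevated esophageal IgE-pathway
#' activity); `default_fi_effect()` returns the FI-specific fold
#' changes applied to `EoE_FI` relative to `EoE_no_FI`: the seven transcripts
#' reported down-regulated in patients with food impactions (mast-cell and
#' Th2 markers `CPA3`, `FCER1B`, `CCL2`, `IL4`, `IL5`; motility regulators
#' `NOS2`, `HIF1A`) at folds between 0.3 and 0.5.
#'
#' @return Named numeric vector mapping gene to fold factor.
#' @export
default_eoe_effect <- function() {
  c(CCL26 = 12, CPA3 = 2, FCER1B = 2, CCL2 = 1.5, IL4 = 2, IL5 = 2,
    IL13 = 6, NOS2 = 1.5, HIF1A = 1.2, GENE_010 = 3, GENE_011 = 0.5,
    GENE_012 = 2)
}

#' @rdname default_eoe_effect
#' @export
default_fi_effect <- function() {
  c(CPA3 = 0.3, FCER1B = 0.35, CCL2 = 0.4, IL4 = 0.4, IL5 = 0.45,
    NOS2 = 0.5, HIF1A = 0.5)
}
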