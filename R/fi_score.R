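#' Transcript weights from fold difference and adjusted significance
#'
#' Raw weight `w_g = log2FD_g * (-log10 q_g)` for genes whose adjusted
#' significance passes `q_g < alpha`, zero otherwise; weights are then L1
#' normalized so `sum(|w|) = 1`, preserving signs (transcripts
#' down-regulated in the FI group get negative weights). The product is the
#' simplest monotone combination of the two volcano-plot axes.
#'
#' @param de A `de_result` from [run_de()] containing the FI-vs-no-FI
#'   contrast.
#' @param alpha Significance gate on the adjusted p (default 0.05).
#' @param fd_col,q_col Columns holding the contrast's fold difference and
#'   adjusted significance.
#' @return A list of class `transcript_weights`: `weights` (named vector
#'   over all genes, zeros included), `alpha`, `norm_const` (the L1 mass of
#'   the raw weights).
#' @export
compute_transcript_weights <- function(de, alpha = 0.05,
                                       fd_col = "log2fd_fi_vs_nofi",
                                       q_col = "q_fi_vs_nofi") {
  if (!all(c(fd_col, q_col, "gene") %in% names(de)))
    stop("DE result lacks the FI-vs-no-FI contrast columns")
  w <- ifelse(de[[q_col]] < alpha, de[[fd_col]] * (-log10(de[[q_col]])), 0)
  names(w) <- de$gene
  l1 <- sum(abs(w))
  if (l1 == 0)
    stop("empty signature: no gene passes alpha = ", alpha)
  structure(list(weights = w / l1, alpha = alpha, norm_const = l1),
            class = "transcript_weights")
}

#' Raw composite FI-score
#'
#' A one-factor projection with fixed loadings: per scored patient `p`,
#' `s_p = sum_g w_g * z_{g,p}` where `z_{g,p}` standardizes
#' `log2(normalized + 1)` per gene across the scored cohort (sample SD).
#' Scoring is restricted to the EoE cohort — controls are never scored.
#' Genes with zero variance across the cohort contribute zero.
#'
#' @param norm A `normalized_matrix`.
#' @param weights A `transcript_weights` (or named numeric vector).
#' @param cohort Sample ids (or logical/integer index into columns) of the
#'   scored EoE cohort; at least 3 samples.
#' @return Named numeric vector of raw scores over the cohort.
#' @export
compute_raw_fi_score <- function(norm, weights, cohort) {
  w <- if (inherits(weights, "transcript_weights")) weights$weights else weights
  expr <- log_expression(norm)[, cohort, drop = FALSE]
  if (ncol(expr) < 3)
    stop("scored cohort must have >= 3 samples (standardization undefined)")
  genes <- intersect(names(w), rownames(expr))
  w <- w[genes]
  z <- t(scale(t(expr[genes, , drop = FALSE])))  # per-gene, sample SD
  z[is.na(z)] <- 0  # zero-variance genes carry no information
  stats::setNames(as.numeric(crossprod(matrix(w, ncol = 1), z)),
                  colnames(z))
}

#' Standardize scores to mean 0, SD 1
#'
#' `(s - mean) / SD` over the scored cohort, sample SD; affine-invariant.
#'
#' @param scores Numeric vector, length >= 3.
#' @return Standardized scores.
#' @export
standardize_scores <- function(scores) {
  if (length(scores) < 3) stop("need >= 3 scores to standardize")
  s <- stats::sd(scores)
  if (s == 0) stop("degenerate score distribution: zero SD")
  (scores - mean(scores)) / s
}

#' Threshold calls on the standardized FI-score
#'
#' `score >= cutoff` is called FI-positive (the boundary is positive).
#'
#' @param scores Standardized scores.
#' @param cutoff Finite numeric cutoff.
#' @return Logical vector of FI calls.
#' @export
call_fi <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  scores >= cutoff
}

#' End-to-end FI signature on an EoE cohort
#'
#' Runs the scoring loop on labeled data: transcript weights from the
#' FI-vs-no-FI contrast of `de`, raw composite scores over the EoE samples,
#' standardization, ROC against the FI labels, cutoff selection, and calls.
#' Weights are computed in-sample on the same cohort that is scored;
#' [loo_fi_scores()] provides the leave-one-out alternative.
#'
#' @param norm A `normalized_matrix`.
#' @param group Group label per sample aligned with `norm` columns.
#' @param de Optional precomputed `de_result`; computed from `norm` and
#'   `group` when `NULL`.
#' @param alpha Weight gate, default 0.05.
#' @param cutoff_policy `"youden"`, `"max_specificity"`, or a fixed numeric
#'   cutoff.
#' @return A list of class `fi_score_result`: `weights`, `raw`,
#'   `standardized`, `cohort_mean`, `cohort_sd`, `roc`, `cutoff`,
#'   `cutoff_policy`, `calls` (named logical over EoE samples).
#' @export
fi_signature <- function(norm, group, de = NULL, alpha = 0.05,
                         cutoff_policy = "youden") {
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  if (is.null(de)) de <- run_de(norm, group)
  weights <- compute_transcript_weights(de, alpha = alpha)
  cohort <- colnames(norm$values)[group %in% c("EoE_no_FI", "EoE_FI")]
  raw <- compute_raw_fi_score(norm, weights, cohort)
  std <- standardize_scores(raw)
  labels <- group[match(cohort, colnames(norm$values))] == "EoE_FI"
  roc <- roc_result(std, labels,
                    policy = if (is.numeric(cutoff_policy)) "fixed"
                             else cutoff_policy,
                    fixed_cutoff = if (is.numeric(cutoff_policy))
                      cutoff_policy else NULL)
  structure(list(weights = weights, raw = raw, standardized = std,
                 cohort_mean = mean(raw), cohort_sd = stats::sd(raw),
                 roc = roc, cutoff = roc$cutoff,
                 cutoff_policy = if (is.numeric(cutoff_policy)) "fixed"
                                 else cutoff_policy,
                 calls = call_fi(std, roc$cutoff)),
            class = "fi_score_result")
}

#' Leave-one-out FI scores
#'
#' For each EoE patient in turn: recompute the differential expression,
#' transcript weights, and per-gene standardization on the cohort without
#' that patient, then score the held-out patient against that model.
#' Held-out folds whose reduced cohort yields an empty signature score 0
#' (no classifier, no discrimination). The LOO AUC is expected to sit at or
#' below the in-sample AUC on average.
#'
#' @inheritParams fi_signature
#' @return List with `scores` (named, one per EoE sample), `labels`
#'   (logical FI status), and `auc`.
#' @export
loo_fi_scores <- function(norm, group, alpha = 0.05) {
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  samples <- colnames(norm$values)
  cohort <- samples[group %in% c("EoE_no_FI", "EoE_FI")]
  expr <- log_expression(norm)
  scores <- stats::setNames(numeric(length(cohort)), cohort)
  for (s in cohort) {
    keep <- setdiff(samples, s)
    sub <- norm
    sub$values <- norm$values[, keep, drop = FALSE]
    grp_sub <- group[match(keep, samples)]
    sc <- tryCatch({
      de <- run_de(sub, grp_sub)
      w <- compute_transcript_weights(de, alpha = alpha)$weights
      train <- intersect(keep, cohort)
      mu <- rowMeans(expr[names(w), train, drop = FALSE])
      sdv <- apply(expr[names(w), train, drop = FALSE], 1, stats::sd)
      z <- (expr[names(w), s] - mu) / ifelse(sdv == 0, 1, sdv)
      z[sdv == 0] <- 0
      sum(w * z)
    }, error = function(e) {
      if (grepl("empty signature", conditionMessage(e))) 0
      else stop(e)
    })
    scores[s] <- sc
  }
  labels <- group[match(cohort, samples)] == "EoE_FI"
  list(scores = scores, labels = labels,
       auc = tryCatch(auc(scores, labels), error = function(e) NA_real_))
}
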