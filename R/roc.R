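#' Area under the ROC curve
#'
#' The Mann-Whitney probability `P(score_pos > score_neg) + 0.5 P(equal)`,
#' computed from midranks (tied pairs receive half credit); identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical (or 0/1) class labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC operating points
#'
#' One operating point per distinct threshold (calls are `score >=
#' threshold`), from (0,0) at a threshold above the maximum score to (1,1)
#' below the minimum; monotone nondecreasing in both coordinates.
#'
#' @inheritParams auc
#' @return `data.frame` with `threshold`, `sensitivity`, `fpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, fpr = fpr)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUC value in `[0, 1]`.
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return The standard error.
#' @export
auc_se_hanley_mcneil <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' ROC-derived cutoff selection
#'
#' Candidate cutoffs are the realized midpoints between adjacent distinct
#' scores, plus one below the minimum (everything called positive) and one
#' above the maximum (nothing called). `youden` maximizes
#' `sensitivity + specificity - 1`; `max_specificity` takes, among cutoffs
#' with specificity exactly 1, the one maximizing sensitivity (falling back
#' to a cutoff above the highest negative score, which always exists among
#' the candidates). Ties break toward the lower cutoff.
#'
#' @inheritParams auc
#' @param policy `"youden"` or `"max_specificity"`.
#' @return The selected cutoff (calls are `score >= cutoff`).
#' @export
select_cutoff <- function(scores, labels, policy = c("youden", "max_specificity")) {
  policy <- match.arg(policy)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("cutoff selection needs both classes")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1,
            if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + 1)
  sens <- vapply(cand, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!labels] < t), numeric(1))
  if (policy == "youden") {
    j <- sens + spec - 1
    cand[which.max(j)]  # which.max takes the first (lowest) on ties
  } else {
    ok <- spec == 1
    cand_ok <- cand[ok]
    cand_ok[which.max(sens[ok])]
  }
}

#' Confusion-matrix metrics at a cutoff
#'
#' Sensitivity, specificity, PPV, NPV and the underlying counts. Ratios with
#' a zero denominator are reported as `NA` (missing), never as 0.
#'
#' @param calls Logical calls aligned with `labels`.
#' @param labels Logical true class.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(calls, labels) {
  calls <- as.logical(calls); labels <- as.logical(labels)
  stopifnot(length(calls) == length(labels))
  tp <- sum(calls & labels); fp <- sum(calls & !labels)
  tn <- sum(!calls & !labels); fn <- sum(!calls & labels)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Full ROC result for a score vector
#'
#' Bundles operating points, AUC with Hanley-McNeil SE, the selected (or
#' fixed) cutoff, and the at-cutoff confusion metrics.
#'
#' @inheritParams auc
#' @param policy `"youden"`, `"max_specificity"`, or `"fixed"`.
#' @param fixed_cutoff Cutoff to use when `policy = "fixed"`.
#' @return A list of class `roc_result`.
#' @export
roc_result <- function(scores, labels, policy = "youden",
                       fixed_cutoff = NULL) {
  labels <- as.logical(labels)
  a <- auc(scores, labels)
  cutoff <- if (policy == "fixed") {
    stopifnot(is.numeric(fixed_cutoff))
    fixed_cutoff
  } else select_cutoff(scores, labels, policy)
  cm <- confusion_metrics(call_fi(scores, cutoff), labels)
  structure(list(points = roc_points(scores, labels), auc = a,
                 se = auc_se_hanley_mcneil(a, sum(labels), sum(!labels)),
                 cutoff = cutoff, at_cutoff = cm,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_result")
}
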