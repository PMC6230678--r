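#' Kruskal-Wallis test for k groups
#'
#' Tie-corrected H referenced to a chi-square distribution with k-1 degrees
#' of freedom (midranks throughout; the chi-square approximation is used at
#' all sample sizes). The fully degenerate case — every observation
#' identical — has an undefined tie correction and is defined as H = 0,
#' p = 1 (no evidence of a group difference).
#'
#' @param groups List of >= 2 nonempty numeric vectors, total N >= 3.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("every group must be nonempty")
  if (sum(lengths(groups)) < 3) stop("need total N >= 3")
  invisible(groups)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise rank-mean comparisons on the joint midranks:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t)`; two-sided p from the normal tail,
#' adjusted across the `k(k-1)/2` pairs (Bonferroni by default, Holm by
#' option — the conventions of the post-hoc as usually reported).
#'
#' @param groups List of numeric vectors (named names label the pairs).
#' @param adjust `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return `data.frame` with columns `group1`, `group2`, `z`, `p`, `p_adj`;
#'   `z > 0` means group1 has the larger mean rank.
#' @export
dunns_test <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  check_groups(groups)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)  # midranks
  idx <- rep(seq_along(groups), n)
  rbar <- tapply(r, idx, mean)
  tie_tab <- table(x)
  T_ties <- sum(tie_tab^3 - tie_tab)
  var_term <- N * (N + 1) / 12 - T_ties / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    denom <- sqrt(var_term * (1 / n[i] + 1 / n[j]))
    z[k] <- if (denom == 0) 0 else (rbar[i] - rbar[j]) / denom
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p = p,
             p_adj = stats::p.adjust(p, method = if (adjust == "none") "none"
                                     else adjust),
             stringsAsFactors = FALSE)
}

#' Log2 fold difference of group medians
#'
#' `log2((median_A + c) / (median_B + c))` on the normalized (not log)
#' scale; the pseudocount `c` (default 1) keeps the ratio defined when a
#' median is zero.
#'
#' @param a,b Numeric vectors for the two contrast groups (A vs B).
#' @param pseudocount Nonnegative pseudocount, default 1.
#' @return The log2 fold difference (positive means higher in A).
#' @export
fold_difference <- function(a, b, pseudocount = 1) {
  if (!length(a) || !length(b)) stop("both contrast groups must be nonempty")
  log2((stats::median(a) + pseudocount) / (stats::median(b) + pseudocount))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method Adjustment method, default `"BH"`.
#' @return Adjusted q-values.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

CONTRASTS <- list(
  fi_vs_nofi = c("EoE_FI", "EoE_no_FI"),
  fi_vs_control = c("EoE_FI", "Control"),
  nofi_vs_control = c("EoE_no_FI", "Control")
)

#' Per-gene three-group differential expression
#'
#' For every endogenous gene: the tie-corrected Kruskal-Wallis H and p over
#' the three clinical groups; Dunn's z and (Bonferroni-)adjusted p for each
#' pairwise contrast; the median-based log2 fold difference per contrast on
#' the normalized scale; and a BH-adjusted q over genes for the
#' FI-vs-no-FI contrast (the adjusted significance that feeds the transcript
#' weights — one point per transcript, as on a volcano plot). The q family
#' can be switched to the per-gene Dunn-adjusted p via
#' `q_source = "dunn_adjusted"`.
#'
#' @param norm A `normalized_matrix` (see [normalize_lanes()]).
#' @param group Group label per sample (`Control`, `EoE_no_FI`, `EoE_FI`),
#'   aligned with the columns of `norm$values`.
#' @param dunn_adjust Pair-family adjustment for Dunn's test.
#' @param q_source `"bh_over_genes"` (default) or `"dunn_adjusted"`.
#' @param pseudocount Pseudocount for [fold_difference()].
#' @return A `data.frame` of class `de_result`, one row per gene, with
#'   columns `gene`, `H`, `p_kw`, `z_*`, `p_*`, `p_adj_*`, `log2fd_*` for
#'   each contrast, and `q_fi_vs_nofi`.
#' @export
run_de <- function(norm, group, dunn_adjust = "bonferroni",
                   q_source = c("bh_over_genes", "dunn_adjusted"),
                   pseudocount = 1) {
  q_source <- match.arg(q_source)
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  if (length(group) != ncol(norm$values))
    stop("group labels do not align with normalized samples")
  vals <- norm$values
  present <- levels(group)[levels(group) %in% group]
  contrasts <- Filter(function(ct) all(ct %in% present), CONTRASTS)
  if (!length(contrasts)) stop("need at least two groups present")

  rows <- lapply(rownames(vals), function(g) {
    v <- vals[g, ]
    by_grp <- split(v, group)[present]
    kw <- kruskal_wallis(by_grp)
    dn <- dunns_test(by_grp, adjust = dunn_adjust)
    row <- list(gene = g, H = kw$H, p_kw = kw$p)
    for (nm in names(contrasts)) {
      ct <- contrasts[[nm]]
      hit <- which((dn$group1 == ct[1] & dn$group2 == ct[2]) |
                   (dn$group1 == ct[2] & dn$group2 == ct[1]))
      sgn <- if (dn$group1[hit] == ct[1]) 1 else -1
      row[[paste0("z_", nm)]] <- sgn * dn$z[hit]
      row[[paste0("p_", nm)]] <- dn$p[hit]
      row[[paste0("p_adj_", nm)]] <- dn$p_adj[hit]
      row[[paste0("log2fd_", nm)]] <-
        fold_difference(v[group == ct[1]], v[group == ct[2]], pseudocount)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  de <- do.call(rbind, rows)
  if ("p_fi_vs_nofi" %in% names(de)) {
    de$q_fi_vs_nofi <- if (q_source == "bh_over_genes")
      adjust_pvalues(de$p_fi_vs_nofi) else de$p_adj_fi_vs_nofi
  }
  class(de) <- c("de_result", "data.frame")
  de
}
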