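#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass two-sided definition: the sum, over all tables with the
#' observed margins, of every hypergeometric probability not exceeding that
#' of the observed table (with the conventional `1 + 1e-7` relative
#' tolerance on the comparison). Masses are computed with log-factorials
#' (`lchoose`), so arbitrary cohort sizes are safe. A table with a zero
#' margin admits only one configuration and has p = 1.
#'
#' @param tab A 2x2 matrix of nonnegative integer counts (rows = groups,
#'   columns = trait present/absent), or the four counts `a, b, c, d` given
#'   row-wise.
#' @return The two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of nonnegative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(N, c1)
  log_obs <- lchoose(r1, a) + lchoose(r2, c) - lchoose(N, c1)
  min(1, sum(exp(logp[logp <= log_obs + log(1 + 1e-7)])))
}

#' Cohort characteristics table with pairwise exact statistics
#'
#' For each binary (tri-state yes/no/missing) trait: per-group `n/N` counts
#' and percentage (missing values excluded from the denominator) and the
#' two-sided Fisher exact p for every group pair. For each numeric trait:
#' per-group median (range), the Kruskal-Wallis p across groups, and Dunn's
#' adjusted p per pair. Traits listed but absent from the table are skipped
#' with a warning.
#'
#' @param meta A `clinical_table` data.frame (see
#'   [validate_clinical_table()]).
#' @param groups Group labels to compare, in display order.
#' @param binary_traits,numeric_traits Trait columns; by default binary
#'   traits are auto-detected (columns whose non-missing values are all
#'   yes/no) and numeric traits are the numeric columns other than ids.
#' @return A `data.frame` with one row per trait: `trait`, `type`, one
#'   summary column per group, and one `p_<g1>_vs_<g2>` column per pair
#'   (plus `p_kw` for numeric traits). Full-precision p-values; percentages
#'   rounded half-up to integers for display.
#' @export
cohort_table <- function(meta, groups = c("EoE_FI", "EoE_no_FI", "Control"),
                         binary_traits = NULL, numeric_traits = NULL) {
  meta <- as.data.frame(meta)
  groups <- intersect(groups, unique(meta$group))
  if (length(groups) < 2) stop("need >= 2 groups present")
  skip_cols <- c("sample_id", "group")
  if (is.null(binary_traits))
    binary_traits <- names(Filter(function(col)
      !is.numeric(col) && all(col[!is.na(col)] %in% c("yes", "no")) &&
        any(!is.na(col)),
      meta[setdiff(names(meta), skip_cols)]))
  if (is.null(numeric_traits))
    numeric_traits <- names(Filter(is.numeric,
                                   meta[setdiff(names(meta), skip_cols)]))
  absent <- setdiff(c(binary_traits, numeric_traits), names(meta))
  if (length(absent)) {
    warning("trait(s) absent from table, skipped: ",
            paste(absent, collapse = ", "))
    binary_traits <- setdiff(binary_traits, absent)
    numeric_traits <- setdiff(numeric_traits, absent)
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pair_col <- vapply(pairs, function(p) paste0("p_", p[1], "_vs_", p[2]),
                     character(1))

  half_up <- function(x) floor(x + 0.5)
  rows <- list()
  for (tr in binary_traits) {
    row <- list(trait = tr, type = "binary", p_kw = NA_real_)
    for (g in groups) {
      v <- meta[[tr]][meta$group == g]
      n <- sum(v == "yes", na.rm = TRUE); N <- sum(!is.na(v))
      row[[g]] <- if (N == 0) "" else
        sprintf("%d/%d (%d%%)", n, N, half_up(100 * n / N))
    }
    for (i in seq_along(pairs)) {
      p2 <- pairs[[i]]
      cells <- vapply(p2, function(g) {
        v <- meta[[tr]][meta$group == g]
        c(sum(v == "yes", na.rm = TRUE),
          sum(v == "no", na.rm = TRUE))
      }, numeric(2))
      # a group with no assessed samples cannot be compared
      row[[pair_col[i]]] <- if (any(colSums(cells) == 0)) NA_real_ else
        fisher_exact_two_sided(t(cells))
    }
    rows[[length(rows) + 1]] <- row
  }
  for (tr in numeric_traits) {
    row <- list(trait = tr, type = "numeric")
    by_grp <- lapply(groups, function(g) {
      v <- meta[[tr]][meta$group == g]
      v[!is.na(v)]
    })
    names(by_grp) <- groups
    for (g in groups) {
      v <- by_grp[[g]]
      row[[g]] <- if (!length(v)) "" else
        sprintf("%g (%g-%g)", stats::median(v), min(v), max(v))
    }
    usable <- lengths(by_grp) > 0
    row$p_kw <- if (sum(usable) >= 2)
      kruskal_wallis(by_grp[usable])$p else NA_real_
    dn <- if (sum(usable) >= 2) dunns_test(by_grp[usable]) else NULL
    for (i in seq_along(pairs)) {
      p2 <- pairs[[i]]
      hit <- if (is.null(dn)) integer(0) else
        which((dn$group1 == p2[1] & dn$group2 == p2[2]) |
              (dn$group1 == p2[2] & dn$group2 == p2[1]))
      row[[pair_col[i]]] <- if (length(hit)) dn$p_adj[hit] else NA_real_
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  cols <- c("trait", "type", groups, "p_kw", pair_col)
  out[, cols[cols %in% names(out)], drop = FALSE]
}
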