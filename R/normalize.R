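#' Geometric mean
#'
#' `exp(mean(log(x)))` over the supplied values. Zeros are not admissible
#' under the default policy; control-probe callers use
#' `zero_policy = "pseudocount"`, which adds 0.5 to every value whenever a
#' zero is present (keeping the geometric mean defined without perturbing
#' typical counts).
#'
#' @param x Nonnegative numeric values, nonempty.
#' @param zero_policy `"error"` (default) or `"pseudocount"`.
#' @return The geometric mean.
#' @export
geometric_mean <- function(x, zero_policy = c("error", "pseudocount")) {
  zero_policy <- match.arg(zero_policy)
  if (length(x) == 0) stop("geometric mean of empty input")
  if (any(x < 0)) stop("geometric mean needs nonnegative values")
  if (all(x == 0)) stop("geometric mean undefined: all values zero")
  if (any(x == 0)) {
    if (zero_policy == "error") stop("geometric mean undefined: zero value")
    x <- x + 0.5
  }
  exp(mean(log(x)))
}

#' Background subtraction
#'
#' Estimates per-lane nonspecific background from the negative-control
#' probes and floors subtracted counts at zero: `adjusted = max(0, count - b)`
#' with `b = mean(negatives)` (default) or `mean + 2 * sd` (sample SD), or
#' `b = 0` for `method = "none"` (matrix-only input without negatives).
#'
#' @param counts Numeric vector/matrix of one lane's probe counts.
#' @param negatives The lane's negative-control counts (required unless
#'   `method = "none"`).
#' @param method `"mean"`, `"mean2sd"`, or `"none"`.
#' @return List with `adjusted` (same shape as `counts`) and `background`
#'   (the subtracted estimate `b`).
#' @export
subtract_background <- function(counts, negatives = NULL,
                                method = c("mean", "mean2sd", "none")) {
  method <- match.arg(method)
  if (method == "none") return(list(adjusted = counts, background = 0))
  if (is.null(negatives) || length(negatives) < 1)
    stop("background method '", method, "' requires negative-control counts")
  b <- switch(method,
              mean = mean(negatives),
              mean2sd = mean(negatives) +
                2 * (if (length(negatives) > 1) stats::sd(negatives) else 0))
  list(adjusted = pmax(0, counts - b), background = b)
}

scale_factors <- function(mat, probes, zero_policy = "pseudocount") {
  gm <- apply(mat[probes, , drop = FALSE], 2, function(v) {
    if (all(v == 0)) return(0)
    geometric_mean(v, zero_policy = zero_policy)
  })
  valid <- gm > 0
  grand <- exp(mean(log(gm[valid])))
  factor <- ifelse(valid, grand / gm, NA_real_)
  list(factor = factor, lane_geomean = gm, grand_geomean = grand)
}

#' Control-based normalization of a raw count set
#'
#' The platform-conventional three stages, in order: (1) per-lane background
#' subtraction from the negative controls; (2) scaling each lane by
#' `grand geometric mean of lane positive-control geomeans / this lane's
#' positive geomean`; (3) the same construction with the housekeeping
#' probes. Lanes whose positive or housekeeping factor falls outside
#' `qc_range` are flagged (reported, not dropped); a lane whose housekeeping
#' geometric mean is zero after subtraction cannot be normalized and is
#' excluded with a warning. By construction the housekeeping geometric mean
#' is identical across retained lanes afterwards.
#'
#' @param raw A [raw_count_set()] (or a numeric probes-by-lanes matrix via
#'   [normalize_matrix()]).
#' @param background Background method passed to [subtract_background()].
#' @param use_positives,use_housekeeping Disable a scaling stage (needed when
#'   the input matrix carries no control probes).
#' @param qc_range Acceptable scale-factor window, default `c(0.3, 3)`.
#' @return An object of class `normalized_matrix`: `values` (endogenous
#'   genes x samples), `control_values` (normalized control probes),
#'   `pos_factor`, `hk_factor`, `background`, `qc_flags`, `excluded`.
#' @export
normalize_lanes <- function(raw, background = c("mean", "mean2sd", "none"),
                            use_positives = TRUE, use_housekeeping = TRUE,
                            qc_range = c(0.3, 3)) {
  stopifnot(inherits(raw, "raw_count_set"))
  normalize_matrix(raw$counts, raw$annotation, background = background,
                   use_positives = use_positives,
                   use_housekeeping = use_housekeeping, qc_range = qc_range)
}

#' @rdname normalize_lanes
#' @param counts Numeric probes-by-lanes matrix (need not be integer, so a
#'   normalized matrix can be re-normalized, e.g. in idempotence checks).
#' @param annotation The matching [probe_annotation()].
#' @export
normalize_matrix <- function(counts, annotation,
                             background = c("mean", "mean2sd", "none"),
                             use_positives = TRUE, use_housekeeping = TRUE,
                             qc_range = c(0.3, 3)) {
  background <- match.arg(background)
  counts <- as.matrix(counts)
  neg <- probes_of_class(annotation, "Negative")
  pos <- probes_of_class(annotation, "Positive")
  hk <- probes_of_class(annotation, "Housekeeping")
  endo <- probes_of_class(annotation, "Endogenous")
  if (use_positives && length(pos) == 0)
    stop("panel has no Positive probes; set use_positives = FALSE")
  if (use_housekeeping && length(hk) == 0)
    stop("panel has no Housekeeping probes; set use_housekeeping = FALSE")
  if (background != "none" && length(neg) == 0)
    stop("background method '", background,
         "' requires Negative probes (set background = \"none\")")

  lanes <- colnames(counts)
  adj <- counts
  bkg <- stats::setNames(numeric(length(lanes)), lanes)
  for (l in lanes) {
    sb <- subtract_background(counts[, l], counts[neg, l], method = background)
    adj[, l] <- sb$adjusted
    bkg[l] <- sb$background
  }

  pos_factor <- stats::setNames(rep(1, length(lanes)), lanes)
  if (use_positives) {
    sf <- scale_factors(adj, pos)
    pos_factor <- sf$factor
    adj <- sweep(adj, 2, pos_factor, `*`)
  }

  hk_factor <- stats::setNames(rep(1, length(lanes)), lanes)
  excluded <- character(0)
  if (use_housekeeping) {
    hk_gm <- apply(adj[hk, , drop = FALSE], 2, function(v)
      if (all(v == 0)) 0 else geometric_mean(v, zero_policy = "pseudocount"))
    dead <- hk_gm == 0
    if (any(dead)) {
      warning("lane(s) with zero housekeeping signal excluded: ",
              paste(lanes[dead], collapse = ", "))
      excluded <- lanes[dead]
      adj <- adj[, !dead, drop = FALSE]
      lanes <- lanes[!dead]
      pos_factor <- pos_factor[!dead]
      bkg <- bkg[!dead]
    }
    sf <- scale_factors(adj, hk)
    hk_factor <- sf$factor
    adj <- sweep(adj, 2, hk_factor, `*`)
  }

  flags <- lapply(stats::setNames(lanes, lanes), function(l) {
    f <- character(0)
    if (pos_factor[l] < qc_range[1] || pos_factor[l] > qc_range[2])
      f <- c(f, "positive_factor_out_of_range")
    if (hk_factor[l] < qc_range[1] || hk_factor[l] > qc_range[2])
      f <- c(f, "housekeeping_factor_out_of_range")
    f
  })
  structure(
    list(values = adj[endo, , drop = FALSE],
         control_values = adj[c(hk, pos, neg), , drop = FALSE],
         annotation = annotation,
         pos_factor = pos_factor, hk_factor = hk_factor, background = bkg,
         qc_flags = flags, excluded = excluded),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "endogenous genes x",
      ncol(x$values), "samples\n")
  nf <- sum(lengths(x$qc_flags) > 0)
  cat("  flagged lanes:", nf, " excluded:", length(x$excluded), "\n")
  invisible(x)
}

#' Log2-transformed normalized expression
#'
#' `log2(normalized + 1)` — the variance-stabilized scale on which rank
#' tests are invariant and the composite score standardizes per gene.
#'
#' @param norm A `normalized_matrix`.
#' @return Numeric matrix, genes x samples.
#' @export
log_expression <- function(norm) log2(norm$values + 1)
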