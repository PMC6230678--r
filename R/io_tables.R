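delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a probe annotation table
#'
#' TSV/CSV with columns `probe`, `class`, and optionally `accession` and
#' `concentration` (fM, positives only).
#'
#' @param path Path to the annotation file.
#' @return A [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (!all(c("probe", "class") %in% names(df)))
    stop("annotation needs 'probe' and 'class' columns")
  probe_annotation(df$probe, df$class,
                   if ("accession" %in% names(df)) df$accession else NA,
                   if ("concentration" %in% names(df)) df$concentration else NA)
}

#' @rdname read_probe_annotation
#' @param ann A [probe_annotation()] to write.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a samples-by-probes count matrix with its annotation
#'
#' First column is the probe name, remaining columns are lanes. Probes are
#' matched to the annotation by exact name; probes absent from the
#' annotation are an error listing the offending names; duplicated probe
#' rows are an error. If the matched panel carries no `Positive` or
#' `Negative` probes a QC warning is raised (control-based normalization
#' stages must then be disabled).
#'
#' @param path Count matrix TSV/CSV.
#' @param annotation_path Probe annotation TSV/CSV (see
#'   [read_probe_annotation()]).
#' @return A [raw_count_set()].
#' @export
read_count_matrix <- function(path, annotation_path) {
  ann <- if (inherits(annotation_path, "probe_annotation")) annotation_path
         else read_probe_annotation(annotation_path)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes))
    stop("duplicated probe row(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  missing <- setdiff(probes, ann$probe)
  if (length(missing))
    stop("probe(s) absent from annotation: ", paste(missing, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- probes
  ann_sub <- ann[ann$probe %in% probes, , drop = FALSE]
  class(ann_sub) <- class(ann)
  cls <- table(factor(ann_sub$class, levels = PROBE_CLASSES))
  if (cls[["Positive"]] == 0 || cls[["Negative"]] == 0)
    warning("QC: matrix has no ", paste(
      PROBE_CLASSES[3:4][c(cls[["Positive"]], cls[["Negative"]]) == 0],
      collapse = " or "), " probes; disable the corresponding ",
      "normalization stages")
  raw_count_set(m, ann_sub)
}

#' @rdname read_count_matrix
#' @param x A [raw_count_set()] to write (probes in rows, lanes in columns).
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(probe = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write clinical metadata tables
#'
#' Missing tri-state values (not assessed) are encoded as empty strings in
#' the file, distinct from `"no"` — denominators in cohort tables exclude
#' them.
#'
#' @param path TSV/CSV path.
#' @return A validated `clinical_table` data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "", na.strings = "")
  validate_clinical_table(df)
  df
}

#' @rdname read_clinical_table
#' @param meta A clinical table to write.
#' @export
write_clinical_table <- function(meta, path) {
  utils::write.table(meta, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a machine-readable pipeline report
#'
#' Writes `report.json` (schema-versioned: weights, scores, ROC metrics,
#' per-sample decisions) plus TSV tables (`normalized.tsv`, `de.tsv`,
#' `scores.tsv`) into `dir`. Re-running on identical inputs reproduces an
#' identical report apart from the timestamp field.
#'
#' @param results A pipeline result list as returned by [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- results$normalized
  utils::write.table(
    data.frame(gene = rownames(norm$values), norm$values, check.names = FALSE),
    file.path(dir, "normalized.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(results$de, file.path(dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$decisions, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  fs <- results$fi
  report <- list(
    schema_version = "1.0",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    weights = as.list(fs$weights$weights[fs$weights$weights != 0]),
    alpha = fs$weights$alpha,
    cutoff = fs$cutoff,
    cutoff_policy = fs$cutoff_policy,
    roc = list(auc = fs$roc$auc, se = fs$roc$se,
               sensitivity = fs$roc$at_cutoff$sensitivity,
               specificity = fs$roc$at_cutoff$specificity,
               ppv = fs$roc$at_cutoff$ppv, npv = fs$roc$at_cutoff$npv,
               n_pos = fs$roc$n_pos, n_neg = fs$roc$n_neg),
    scores = stats::setNames(as.list(fs$standardized), names(fs$standardized)),
    calls = stats::setNames(as.list(unname(fs$calls)), names(fs$calls)),
    qc = list(pos_factor = as.list(norm$pos_factor),
              hk_factor = as.list(norm$hk_factor),
              flags = norm$qc_flags)
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
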