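#' @keywords internal
"_PACKAGE"

PROBE_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")
GROUP_LEVELS <- c("Control", "EoE_no_FI", "EoE_FI")

#' Probe annotation table
#'
#' Builds and validates the probe annotation for a targeted mRNA panel: one
#' row per probe with its code class (`Endogenous`, `Housekeeping`,
#' `Positive`, `Negative`), an accession string, and, for positive-control
#' probes, the nominal spike-in concentration in fM.
#'
#' @param probe Character vector of unique probe names.
#' @param class Character vector of code classes, one of `Endogenous`,
#'   `Housekeeping`, `Positive`, `Negative`.
#' @param accession Character vector of accession ids (free-form).
#' @param concentration Numeric vector of spike concentrations (fM); must be
#'   present and positive for every `Positive` probe, `NA` otherwise.
#' @return A `data.frame` of class `probe_annotation`.
#' @export
probe_annotation <- function(probe, class, accession = NA_character_,
                             concentration = NA_real_) {
  ann <- data.frame(
    probe = as.character(probe),
    class = as.character(class),
    accession = rep_len(as.character(accession), length(probe)),
    concentration = rep_len(as.numeric(concentration), length(probe)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$probe))
    stop("probe names must be unique; duplicated: ",
         paste(unique(ann$probe[duplicated(ann$probe)]), collapse = ", "))
  bad <- setdiff(unique(ann$class), PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe class(es): ", paste(bad, collapse = ", "))
  pos <- ann$class == "Positive"
  if (any(pos & (is.na(ann$concentration) | ann$concentration <= 0)))
    stop("every Positive probe needs a positive spike concentration")
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Raw count set
#'
#' Container for a lanes-by-probes digital count experiment: an integer count
#' matrix (probes in rows, lanes in columns), the probe annotation, and
#' free-form per-lane attributes.
#'
#' @param counts Integer matrix, probes x lanes; rownames are probe names and
#'   must match the annotation exactly, colnames are lane ids.
#' @param annotation A [probe_annotation()].
#' @param lane_attributes Optional named list of per-lane attribute lists
#'   (e.g. parsed RCC header fields).
#' @return An object of class `raw_count_set`.
#' @export
raw_count_set <- function(counts, annotation, lane_attributes = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have probe rownames and lane colnames")
  if (!isTRUE(all(counts >= 0)) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (!identical(sort(rownames(counts)), sort(annotation$probe)))
    stop("count matrix probes do not match annotation probes")
  counts <- counts[annotation$probe, , drop = FALSE]
  if (anyDuplicated(colnames(counts))) stop("lane ids must be unique")
  structure(
    list(counts = counts, annotation = annotation,
         lane_attributes = lane_attributes),
    class = "raw_count_set"
  )
}

#' @export
print.raw_count_set <- function(x, ...) {
  cls <- table(factor(x$annotation$class, levels = PROBE_CLASSES))
  cat("raw_count_set:", ncol(x$counts), "lanes x", nrow(x$counts), "probes\n")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

probes_of_class <- function(annotation, class) {
  annotation$probe[annotation$class == class]
}

#' Validate a clinical metadata table
#'
#' Checks the structural invariants of a clinical table: unique sample ids,
#' group labels restricted to `Control`, `EoE_no_FI`, `EoE_FI`, and
#' nonnegative eosinophil counts where present. Binary clinical fields are
#' tri-state: `"yes"`, `"no"`, or `NA` (missing / not assessed).
#'
#' @param meta A `data.frame` with at least `sample_id` and `group` columns.
#' @return The validated `data.frame`, invisibly classed `clinical_table`.
#' @export
validate_clinical_table <- function(meta) {
  stopifnot(is.data.frame(meta))
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("clinical table needs sample_id and group columns")
  if (anyDuplicated(meta$sample_id)) stop("sample ids must be unique")
  bad <- setdiff(unique(as.character(meta$group)), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (col in intersect(c("eos_proximal", "eos_distal", "eos_max"), names(meta))) {
    v <- meta[[col]]
    if (any(!is.na(v) & v < 0)) stop("eosinophil counts must be >= 0: ", col)
  }
  class(meta) <- unique(c("clinical_table", class(meta)))
  invisible(meta)
}
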