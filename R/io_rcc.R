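#' Read a single-lane RCC file
#'
#' Parses the plain-text per-lane output dialect of digital mRNA counters:
#' comma-separated sections bracketed by `<Tag>`/`</Tag>` lines. `Header`,
#' `Lane_Attributes` and `Code_Summary` are required; any other section is
#' preserved verbatim as an opaque lane attribute. `Code_Summary` rows are
#' `CodeClass,Name,Accession,Count` and counts must be nonnegative integers
#' (a decimal count such as `12.0` is a format error).
#'
#' @param path Path to an RCC file.
#' @return A single-lane [raw_count_set()]; the lane id is taken from the
#'   `ID` field of `Lane_Attributes`.
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sections <- list()
  open_tag <- NULL
  start <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^<(/?)([A-Za-z_]+)>$", ln))[[1]]
    if (length(m)) {
      if (m[2] == "") {
        open_tag <- m[3]; start <- i + 1L
      } else {
        if (is.null(open_tag) || m[3] != open_tag)
          stop("format error: unmatched section tag </", m[3], "> at line ", i)
        sections[[open_tag]] <- list(lines = lines[seq(start, i - 1L)],
                                     start = start)
        open_tag <- NULL
      }
    }
  }
  for (req in c("Header", "Lane_Attributes", "Code_Summary"))
    if (is.null(sections[[req]]))
      stop("format error: missing required section <", req, ">")

  parse_kv <- function(sec) {
    kv <- strsplit(sec$lines[nzchar(sec$lines)], ",", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = ","),
                           character(1)),
                    vapply(kv, `[`, character(1), 1))
  }
  lane_attr <- as.list(parse_kv(sections$Lane_Attributes))
  lane_id <- lane_attr$ID
  if (is.null(lane_id) || !nzchar(lane_id))
    stop("format error: Lane_Attributes has no ID field")

  cs <- sections$Code_Summary
  rows <- cs$lines[nzchar(trimws(cs$lines))]
  offsets <- which(nzchar(trimws(cs$lines)))
  if (length(rows) && grepl("^CodeClass,", rows[1], ignore.case = TRUE)) {
    rows <- rows[-1]; offsets <- offsets[-1]
  }
  if (!length(rows)) stop("format error: Code_Summary has no probe rows")
  parts <- strsplit(rows, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 4))
    stop("format error: Code_Summary row with ", nfield[nfield != 4][1],
         " fields at line ", cs$start + offsets[which(nfield != 4)[1]] - 1L)
  cls <- vapply(parts, `[`, character(1), 1)
  name <- vapply(parts, `[`, character(1), 2)
  acc <- vapply(parts, `[`, character(1), 3)
  cnt_s <- trimws(vapply(parts, `[`, character(1), 4))
  bad <- !grepl("^[0-9]+$", cnt_s)
  if (any(bad))
    stop("format error: non-integer count \"", cnt_s[which(bad)[1]],
         "\" at line ", cs$start + offsets[which(bad)[1]] - 1L)
  counts <- as.integer(cnt_s)

  conc <- rep(NA_real_, length(name))
  pos <- cls == "Positive"
  # platform convention: spike concentration embedded as NAME(conc)
  conc[pos] <- suppressWarnings(
    as.numeric(sub("^.*\\(([0-9.eE+-]+)\\)$", "\\1", name[pos])))
  if (any(pos & is.na(conc)))
    conc[pos & is.na(conc)] <- 128 / 4^(seq_len(sum(pos & is.na(conc))) - 1)

  ann <- probe_annotation(name, cls, acc, conc)
  m <- matrix(counts, ncol = 1, dimnames = list(name, lane_id))
  extra <- sections[setdiff(names(sections),
                            c("Header", "Lane_Attributes", "Code_Summary"))]
  lane_attr$header <- parse_kv(sections$Header)
  if (length(extra))
    lane_attr$extra_sections <- lapply(extra, `[[`, "lines")
  raw_count_set(m, ann,
                lane_attributes = stats::setNames(list(lane_attr), lane_id))
}

#' Write one RCC file per lane
#'
#' Serializes a [raw_count_set()] into the RCC dialect read by [read_rcc()],
#' one file per lane, named `<prefix><lane id>.rcc`.
#'
#' @param x A [raw_count_set()].
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix, default `"lane_"`.
#' @return Invisibly, the written file paths.
#' @export
write_rcc <- function(x, dir, prefix = "lane_") {
  stopifnot(inherits(x, "raw_count_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lane in colnames(x$counts)) {
    p <- file.path(dir, paste0(prefix, lane, ".rcc"))
    con <- file(p, "w")
    writeLines(c("<Header>", "FileVersion,1.7", "SoftwareVersion,fiscope",
                 "</Header>", "", "<Lane_Attributes>", paste0("ID,", lane),
                 "</Lane_Attributes>", "", "<Code_Summary>",
                 "CodeClass,Name,Accession,Count"), con)
    ann <- x$annotation
    writeLines(sprintf("%s,%s,%s,%d", ann$class, ann$probe,
                       ifelse(is.na(ann$accession), "", ann$accession),
                       x$counts[ann$probe, lane]), con)
    writeLines("</Code_Summary>", con)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a directory of RCC files into one count set
#'
#' @param dir Directory containing `*.rcc`/`*.RCC` files.
#' @return A multi-lane [raw_count_set()]; all lanes must share one panel.
#' @export
read_rcc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.[Rr][Cc][Cc]$",
                           full.names = TRUE))
  if (!length(files)) stop("no RCC files found in ", dir)
  lanes <- lapply(files, read_rcc)
  ann <- lanes[[1]]$annotation
  for (l in lanes[-1])
    if (!identical(l$annotation$probe, ann$probe))
      stop("format error: lanes use different probe panels")
  counts <- do.call(cbind, lapply(lanes, `[[`, "counts"))
  attrs <- do.call(c, lapply(lanes, `[[`, "lane_attributes"))
  raw_count_set(counts, ann, lane_attributes = attrs)
}
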