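# Tab-separated readers/writers. Missing cells are an empty field or "NA"
# (case-insensitive) and round-trip exactly; row/column order is preserved
# as given, never sorted.

split_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

parse_num <- function(x) {
  x[toupper(trimws(x)) %in% c("", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("non-numeric value(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a probe-by-sample expression table
#'
#' First column holds probe ids, the header row sample ids. Optional
#' detection p-values sit in paired columns whose header is the sample id
#' followed by `detection_suffix`. Empty fields and `NA` (case-insensitive)
#' mark missing cells.
#'
#' @param path file path of a tab-separated table.
#' @param has_detection_p if `TRUE`, columns named
#'   `<sample><detection_suffix>` are read as detection p-values.
#' @param detection_suffix suffix identifying detection-p columns.
#' @param scale scale flag passed to [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, has_detection_p = FALSE,
                                   detection_suffix = ".Detection.Pval",
                                   scale = c("glog2", "raw")) {
  scale <- match.arg(scale)
  rows <- split_tsv(path)
  header <- rows[[1]]
  ncol_expect <- length(header)
  body <- rows[-1]
  ragged <- which(lengths(body) != ncol_expect)
  if (length(ragged))
    stop("ragged row at line ", ragged[1] + 1L, ": expected ",
         ncol_expect, " fields, found ", length(body[[ragged[1]]]))
  cols <- header[-1]
  if (has_detection_p) {
    is_det <- endsWith(cols, detection_suffix)
    if (!any(is_det))
      stop("has_detection_p = TRUE but no column ends with '",
           detection_suffix, "'")
    det_for <- sub(paste0("\\Q", detection_suffix, "\\E$"), "", cols[is_det])
    samples <- cols[!is_det]
    missing_det <- setdiff(samples, det_for)
    if (length(missing_det))
      stop("no detection-p column for sample(s): ",
           paste(missing_det, collapse = ", "))
  } else {
    is_det <- rep(FALSE, length(cols))
    samples <- cols
  }
  probes <- vapply(body, `[[`, "", 1L)
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  cells <- do.call(rbind, lapply(body, function(r) r[-1]))
  vals <- matrix(parse_num(cells[, !is_det, drop = FALSE]),
                 nrow = length(probes),
                 dimnames = list(probes, samples))
  det <- NULL
  if (has_detection_p) {
    det <- matrix(parse_num(cells[, is_det, drop = FALSE]),
                  nrow = length(probes),
                  dimnames = list(probes, det_for))
    det <- det[, samples, drop = FALSE]
  }
  expression_matrix(vals, detection_p = det, scale = scale)
}

#' Write an expression table readable by [read_expression_matrix()]
#'
#' @param x an [expression_matrix()]
#' @param path output file path
#' @param detection_suffix suffix for detection-p columns (used only when
#'   detection p-values are present).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path,
                                    detection_suffix = ".Detection.Pval") {
  fmt <- function(m) {
    out <- format(m, digits = 17, trim = TRUE, scientific = FALSE)
    out[is.na(m)] <- "NA"
    out
  }
  vals <- fmt(x$values)
  header <- c("probe_id", colnames(x$values))
  body <- cbind(rownames(x$values), vals)
  if (!is.null(x$detection_p)) {
    header <- c(header, paste0(colnames(x$values), detection_suffix))
    body <- cbind(body, fmt(x$detection_p))
  }
  writeLines(c(paste(header, collapse = "\t"),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample_id`, `subject_id`, `arm`,
#' `timepoint`; validated by [study_design()].
#'
#' @param path file path
#' @return a [study_design()]
#' @export
read_study_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  study_design(df)
}

#' @rdname read_study_design
#' @param design a [study_design()] to write
#' @export
write_study_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: `name TAB description TAB member...`; duplicate members
#' within a set are dropped.
#'
#' @param path file path
#' @return a [gene_sets()]
#' @export
read_gmt <- function(path) {
  rows <- split_tsv(path)
  short <- which(lengths(rows) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(rows, `[[`, "", 1L)
  desc <- vapply(rows, `[[`, "", 2L)
  members <- lapply(rows, function(r) unique(r[-(1:2)]))
  names(members) <- nm
  gene_sets(members, desc)
}

#' @rdname read_gmt
#' @param x a [gene_sets()] to write
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Minimal GEO series-matrix reader
#'
#' Convenience for series-matrix exports: metadata lines are prefixed
#' `!`, the numeric table is delimited by the
#' `!series_matrix_table_begin` / `_end` markers, and the first table
#' column holds probe ids. Quotes around fields are stripped.
#'
#' @param path file path (plain text, uncompressed)
#' @param scale scale flag for the returned matrix
#' @return an [expression_matrix()]
#' @export
read_series_matrix <- function(path, scale = c("glog2", "raw")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("series-matrix table markers not found")
  tbl <- lines[(beg + 1L):(end - 1L)]
  rows <- strsplit(gsub('"', "", tbl, fixed = TRUE), "\t", fixed = TRUE)
  header <- rows[[1]][-1]
  body <- rows[-1]
  probes <- vapply(body, `[[`, "", 1L)
  vals <- matrix(parse_num(do.call(rbind, lapply(body, `[`, -1L))),
                 nrow = length(probes), dimnames = list(probes, header))
  expression_matrix(vals, scale = scale)
}
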