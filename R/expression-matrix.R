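#' Probe-by-sample expression matrix
#'
#' Container for a real-valued probes x samples matrix, either on the raw
#' intensity scale or on the variance-stabilized glog2 scale, with optional
#' per-cell detection p-values. Missing cells are encoded as `NA` in
#' `values`; [missing_mask()] exposes them as a logical matrix.
#'
#' @param values numeric matrix with unique, non-empty rownames (probe ids)
#'   and colnames (sample ids).
#' @param detection_p optional numeric matrix of the same dimensions with
#'   entries in \[0, 1\] (per-cell probability that the intensity is
#'   indistinguishable from negative-control background).
#' @param scale `"glog2"` (normalized) or `"raw"` (scanner intensities).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `detection_p` and `scale`.
#' @seealso [read_expression_matrix()], [vsn_normalize()], [knn_impute()]
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' expression_matrix(m)
expression_matrix <- function(values, detection_p = NULL,
                              scale = c("glog2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  # R normalizes a zero-length dimname to NULL, so an empty dimension is
  # exempt from the name requirement
  pid <- rownames(values)
  sid <- colnames(values)
  if ((is.null(pid) && nrow(values) > 0L) ||
      (is.null(sid) && ncol(values) > 0L))
    stop("'values' must have probe rownames and sample colnames")
  if (is.null(pid)) pid <- character(0)
  if (is.null(sid)) sid <- character(0)
  dup <- unique(pid[duplicated(pid)])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)))
      stop("'detection_p' dimensions must match 'values'")
    rng <- suppressWarnings(range(detection_p, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      stop("'detection_p' entries must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(list(values = values, detection_p = detection_p, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(sprintf("  %d missing cell(s)\n", nmiss))
  if (!is.null(x$detection_p)) cat("  detection p-values present\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers
#' @param x an `expression_matrix`
#' @return character vector of ids, in stored order.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Logical mask of missing cells
#' @param x an `expression_matrix`
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(x) is.na(x$values)
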