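#' Named collection of gene sets
#'
#' @param sets named list of character vectors (members; deduplicated).
#' @param descriptions optional character vector, one per set.
#' @return A `gene_sets` object: list with `sets` and `descriptions`.
#' @seealso [read_gmt()], [ora_hypergeometric()]
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("duplicate set name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("'descriptions' must have one entry per set")
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %d..%d members\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)
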