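#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a module gene list.
#' With a universe of N genes of which K belong to the set (after
#' intersecting the set with the universe) and a module of n genes with
#' k in the set, the p-value is the upper-tail hypergeometric
#' probability of observing at least k successes,
#' `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`. P-values are
#' adjusted across the tested sets, Bonferroni by default.
#'
#' @param module_genes character vector of module gene ids (must be a
#'   subset of `universe`).
#' @param universe character vector: all testable genes (e.g. every
#'   gene surviving the detection filter).
#' @param sets a [gene_sets()] collection.
#' @param adjust multiplicity adjustment: `"bonferroni"` (default) or
#'   `"bh"`.
#' @return data.frame per set: `set_name`, `overlap`, `set_size`,
#'   `module_size`, `universe_size`, `p`, `adjusted_p`, `method`,
#'   sorted by increasing p.
#' @export
ora_hypergeometric <- function(module_genes, universe, sets,
                               adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(module_genes, universe)
  if (length(outside))
    stop("module gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  N <- length(universe)
  n <- length(module_genes)
  recs <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(module_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K,
               module_size = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$adjusted_p <- if (adjust == "bonferroni")
    pmin(1, out$p * nrow(out)) else stats::p.adjust(out$p, "BH")
  out$method <- adjust
  out[order(out$p), , drop = FALSE]
}

#' Read a probe-to-gene mapping table
#'
#' Tab-separated with columns `probe_id` and `gene_symbol`; used to
#' collapse probe lists to gene lists before [ora_hypergeometric()]
#' (duplicate probes per gene collapse to one gene).
#'
#' @param path file path
#' @return data.frame `probe_id`, `gene_symbol`.
#' @export
read_probe_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("probe_id", "gene_symbol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' Map probe ids to unique gene symbols
#'
#' @param probes character vector of probe ids
#' @param map data.frame from [read_probe_gene_map()] (or with the same
#'   columns); probes absent from the map are dropped.
#' @return character vector of unique gene symbols.
#' @export
probes_to_genes <- function(probes, map) {
  unique(map$gene_symbol[map$probe_id %in% probes])
}

#' @rdname ora_hypergeometric
#' @param enrichment an enrichment data.frame to write
#' @param path output TSV path
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
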