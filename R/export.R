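#' Cytoscape-compatible network export
#'
#' Writes the supra-threshold part of the network as a tab-separated
#' edge table readable by Cytoscape's table import, a node attribute
#' table, and a SIF file. Each unordered probe pair appears once, with
#' `source` lexicographically before `target`, and only when its weight
#' (soft adjacency or TOM) strictly exceeds `weight_threshold`.
#'
#' @param model a `network_model`; `tom` must be filled when
#'   `weight_kind = "tom"`.
#' @param assignment module labels from [cluster_and_cut()].
#' @param dir output directory (created if needed).
#' @param weight_threshold strict lower bound on exported weights, in
#'   \[0, 1) (default 0.1).
#' @param weight_kind which weight to export: `"adjacency"` (default)
#'   or `"tom"`.
#' @param hub_probes optional character vector marking hub nodes in the
#'   node table.
#' @return invisibly, a list with the written paths `edges`, `nodes`,
#'   `sif`.
#' @export
export_cytoscape <- function(model, assignment, dir,
                             weight_threshold = 0.1,
                             weight_kind = c("adjacency", "tom"),
                             hub_probes = character(0)) {
  weight_kind <- match.arg(weight_kind)
  if (weight_threshold < 0 || weight_threshold >= 1)
    stop("'weight_threshold' must lie in [0, 1)")
  w <- if (weight_kind == "adjacency") model$adjacency else model$tom
  if (is.null(w)) stop("model has no ", weight_kind, " matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- model$probe_ids
  ut <- which(upper.tri(w) & w > weight_threshold, arr.ind = TRUE)
  src <- ids[ut[, 1]]; tgt <- ids[ut[, 2]]
  swap <- src > tgt
  tmp <- src[swap]; src[swap] <- tgt[swap]; tgt[swap] <- tmp
  ord <- order(src, tgt)
  edges <- data.frame(source = src[ord],
                      interaction = rep("co", length(ord)),
                      target = tgt[ord], weight = w[ut][ord],
                      module_source = as.integer(assignment[src[ord]]),
                      module_target = as.integer(assignment[tgt[ord]]),
                      stringsAsFactors = FALSE)
  conn <- connectivity(model, assignment)
  conn$hub <- conn$probe_id %in% hub_probes
  edge_path <- file.path(dir, "edges.tsv")
  node_path <- file.path(dir, "nodes.tsv")
  sif_path <- file.path(dir, "network.sif")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(conn, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(if (nrow(edges)) paste(edges$source, "co", edges$target)
             else character(0), sif_path)
  invisible(list(edges = edge_path, nodes = node_path, sif = sif_path))
}

#' Re-import an exported edge table as a sparse weight matrix
#'
#' Reconstructs the supra-threshold part of the weight matrix from an
#' `edges.tsv` written by [export_cytoscape()]; entries absent from the
#' file are 0.
#'
#' @param path edge TSV path
#' @param probe_ids full probe id vector fixing matrix order
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_cytoscape_edges <- function(path, probe_ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  w <- matrix(0, length(probe_ids), length(probe_ids),
              dimnames = list(probe_ids, probe_ids))
  if (nrow(df)) {
    unknown <- setdiff(unique(c(df$source, df$target)), probe_ids)
    if (length(unknown))
      stop("edge file names unknown probe(s): ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(df))) {
      w[df$source[i], df$target[i]] <- df$weight[i]
      w[df$target[i], df$source[i]] <- df$weight[i]
    }
  }
  w
}

#' Consolidated per-module statistics table
#'
#' Joins module size, hub, connectivity summaries, eigengene test and
#' direction counts into one table (one row per nonzero module),
#' mirroring a per-module results table.
#'
#' @param conn data.frame from [connectivity()].
#' @param hubs data.frame from [hub_genes()].
#' @param signif data.frame from [module_significance()].
#' @param directions data.frame from [module_direction_counts()].
#' @return data.frame: `module`, `size`, `hub_probe`, `kTotal_mean`,
#'   `kWithin_mean`, `kOut_mean`, `t_statistic`, `p`,
#'   `bonferroni_alpha`, `responsive`, `n_up`, `n_down`, `gs_kme_cor`.
#' @export
module_stats_table <- function(conn, hubs, signif, directions) {
  mods <- hubs$module
  agg <- do.call(rbind, lapply(mods, function(m) {
    cc <- conn[conn$module == m, ]
    data.frame(module = m, kTotal_mean = mean(cc$kTotal),
               kWithin_mean = mean(cc$kWithin),
               kOut_mean = mean(cc$kOut))
  }))
  out <- merge(hubs, agg, by = "module")
  out <- merge(out, signif, by = "module")
  out <- merge(out, directions[c("module", "n_up", "n_down")],
               by = "module")
  out[order(out$module),
      c("module", "size", "hub_probe", "kTotal_mean", "kWithin_mean",
        "kOut_mean", "t_statistic", "p", "bonferroni_alpha",
        "responsive", "n_up", "n_down", "gs_kme_cor")]
}
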