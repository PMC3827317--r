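#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression matrix: probes are standardized to mean 0 and
#' sd 1 across samples, the module's probe-by-sample matrix is
#' decomposed by SVD, and the first right singular vector (unit
#' Euclidean norm) is the eigengene. Its sign is fixed so the
#' correlation with the module's mean standardized profile is
#' non-negative. `variance_explained` is the first singular value
#' squared over the total.
#'
#' @param expr an [expression_matrix()] (no missing values).
#' @param assignment module labels from [cluster_and_cut()] (0 =
#'   unassigned, skipped).
#' @return a `module_eigengenes` object: `eigengenes` (module x sample
#'   matrix, rows named `ME<module>`), `variance_explained`,
#'   `module_ids`, `sample_ids`.
#' @export
module_eigengenes <- function(expr, assignment) {
  x <- expr$values
  mods <- sort(setdiff(unique(assignment), 0L))
  if (!length(mods)) stop("no nonzero modules in the assignment")
  me <- matrix(NA_real_, length(mods), ncol(x),
               dimnames = list(paste0("ME", mods), colnames(x)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    idx <- which(assignment == mods[i])
    if (length(idx) < 2)
      stop("module ", mods[i], " has fewer than 2 probes")
    xm <- x[idx, , drop = FALSE]
    sds <- apply(xm, 1, stats::sd)
    if (any(sds == 0))
      stop("zero-variance probe(s) in module ", mods[i], ": ",
           paste(rownames(xm)[sds == 0], collapse = ", "))
    z <- (xm - rowMeans(xm)) / sds
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, variance_explained = ve,
                 module_ids = mods, sample_ids = colnames(x)),
            class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat(sprintf("module_eigengenes: %d module(s) x %d samples\n",
              length(x$module_ids), length(x$sample_ids)))
  cat("variance explained:",
      paste(sprintf("%s %.2f", names(x$variance_explained),
                    x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Module membership (kME)
#'
#' `kME(g, m)` is the Pearson correlation between probe g's profile and
#' module m's eigengene; probes with high |kME| are central module
#' members.
#'
#' @param expr an [expression_matrix()] over the same samples as the
#'   eigengenes.
#' @param eigengenes a [module_eigengenes()] result.
#' @return probe-by-module kME matrix (columns `ME<module>`), entries in
#'   \[-1, 1\].
#' @export
module_membership <- function(expr, eigengenes) {
  x <- expr$values
  if (!identical(colnames(x), eigengenes$sample_ids))
    stop("expression and eigengenes cover different samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance probe(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  kme <- stats::cor(t(x), t(eigengenes$eigengenes))
  dimnames(kme) <- list(rownames(x), rownames(eigengenes$eigengenes))
  kme
}

#' Module-level treatment testing with Bonferroni control
#'
#' Per module, compares the post-LPS (t4) eigengene values of the two
#' arms with a pooled-variance (Student) two-sample t test; a module is
#' treatment-responsive when its p-value falls below the Bonferroni
#' threshold `alpha / M`, M the number of nonzero modules. With M = 38
#' and alpha = 0.05 the threshold is 0.0013 (-log10 = 2.88).
#'
#' @param eigengenes a [module_eigengenes()] result.
#' @param design a [study_design()] covering the eigengene samples.
#' @param alpha familywise error rate (default 0.05).
#' @param welch use Welch rather than pooled-variance t (default FALSE).
#' @return data.frame per module: `module`, `t_statistic`, `df`, `p`,
#'   `bonferroni_alpha`, `responsive`.
#' @export
module_significance <- function(eigengenes, design, alpha = 0.05,
                                welch = FALSE) {
  sidx <- match(eigengenes$sample_ids, design$sample_id)
  if (any(is.na(sidx)))
    stop("sample(s) absent from design: ",
         paste(eigengenes$sample_ids[is.na(sidx)], collapse = ", "))
  dd <- design[sidx, ]
  pl <- dd$timepoint == "t4" & dd$arm == "placebo"
  et <- dd$timepoint == "t4" & dd$arm == "etanercept"
  if (sum(pl) < 2 || sum(et) < 2)
    stop("each arm needs at least 2 post-LPS samples")
  M <- length(eigengenes$module_ids)
  b_alpha <- alpha / M
  out <- data.frame(module = eigengenes$module_ids,
                    t_statistic = NA_real_, df = NA_real_, p = NA_real_,
                    bonferroni_alpha = b_alpha, responsive = NA)
  for (i in seq_len(M)) {
    e <- eigengenes$eigengenes[i, ]
    tt <- stats::t.test(e[pl], e[et], var.equal = !welch)
    out$t_statistic[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p[i] <- tt$p.value
  }
  out$responsive <- out$p < b_alpha
  out
}

#' Hub genes and gene-significance/module-membership coupling
#'
#' Per nonzero module, reports (i) the hub probe, the member with
#' maximal within-module connectivity kWithin (ties broken by larger
#' |kME| for the module, then lexicographic probe id), and (ii) the
#' Pearson correlation between |gene significance| and the module's kME
#' over its members (NA for modules with fewer than 3 members, where the
#' correlation is not meaningful).
#'
#' @param connectivity data.frame from [connectivity()].
#' @param kme kME matrix from [module_membership()].
#' @param gene_significance named per-probe statistic (e.g. the placebo
#'   paired-LPS t); absolute values are used.
#' @param assignment module labels.
#' @return data.frame per module: `module`, `size`, `hub_probe`,
#'   `gs_kme_cor`.
#' @export
hub_genes <- function(connectivity, kme, gene_significance, assignment) {
  probes <- connectivity$probe_id
  if (!identical(probes, rownames(kme)) ||
      !identical(probes, names(assignment)) ||
      !all(probes %in% names(gene_significance)))
    stop("connectivity, kME, gene significance and assignment must ",
         "cover the same probes in the same order")
  gs <- abs(gene_significance[probes])
  mods <- sort(setdiff(unique(assignment), 0L))
  out <- data.frame(module = mods, size = NA_integer_,
                    hub_probe = NA_character_, gs_kme_cor = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mods)) {
    idx <- which(assignment == mods[i])
    kw <- connectivity$kWithin[idx]
    akme <- abs(kme[idx, paste0("ME", mods[i])])
    ord <- order(-kw, -akme, probes[idx])
    out$size[i] <- length(idx)
    out$hub_probe[i] <- probes[idx][ord[1]]
    if (length(idx) >= 3)
      out$gs_kme_cor[i] <- stats::cor(gs[idx], kme[idx, paste0("ME", mods[i])])
  }
  out
}

#' Per-module counts of induced and reduced probes
#'
#' Counts module members whose log2 fold change strictly exceeds
#' `lfc_threshold` (induced, `n_up`) or falls strictly below
#' `-lfc_threshold` (reduced, `n_down`); probes exactly at the threshold
#' count in neither.
#'
#' @param de a `de_result` covering all assigned probes.
#' @param assignment module labels.
#' @param lfc_threshold log2 fold-change threshold (default 0.5).
#' @return data.frame per module: `module`, `size`, `n_up`, `n_down`.
#' @export
module_direction_counts <- function(de, assignment, lfc_threshold = 0.5) {
  assigned <- names(assignment)[assignment > 0]
  missing <- setdiff(assigned, de$probe_id)
  if (length(missing))
    stop("probe(s) missing from the DE result: ",
         paste(missing, collapse = ", "))
  lfc <- stats::setNames(de$log2_fc, de$probe_id)
  mods <- sort(setdiff(unique(assignment), 0L))
  out <- data.frame(module = mods, size = NA_integer_,
                    n_up = NA_integer_, n_down = NA_integer_)
  for (i in seq_along(mods)) {
    v <- lfc[names(assignment)[assignment == mods[i]]]
    out$size[i] <- length(v)
    out$n_up[i] <- sum(v > lfc_threshold)
    out$n_down[i] <- sum(v < -lfc_threshold)
  }
  out
}

#' @rdname module_eigengenes
#' @param x a `module_eigengenes` object to write
#' @param path output TSV path (module x sample)
#' @export
write_eigengenes <- function(x, path) {
  utils::write.table(
    data.frame(module = rownames(x$eigengenes),
               variance_explained = x$variance_explained,
               x$eigengenes, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
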