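#' Parameters of the weighted co-expression network
#'
#' @param beta soft-threshold power (>= 1); adjacency is `|cor|^beta`.
#' @param min_module_size smallest allowed module (default 30; the study
#'   reports modules "encompassing more than 30 transcripts").
#' @param rsq_target scale-free topology fit index sought by
#'   [pick_soft_threshold()] (default 0.85).
#' @param cut_height_quantile quantile of dendrogram merge heights that
#'   bounds the static cut scan in [cluster_and_cut()] (default 0.99).
#' @param gap minimum merge-height break that splits a dendrogram branch
#'   (on the 1 - TOM scale, default 0.1).
#' @param attach_frac fraction of a module core's median internal TOM a
#'   probe must reach to be attached to that module (default 0.5).
#' @return a `network_params` list.
#' @export
network_params <- function(beta = 6, min_module_size = 30,
                           rsq_target = 0.85, cut_height_quantile = 0.99,
                           gap = 0.1, attach_frac = 0.5) {
  if (beta < 1) stop("'beta' must be at least 1")
  if (min_module_size < 2) stop("'min_module_size' must be at least 2")
  if (rsq_target <= 0 || rsq_target >= 1)
    stop("'rsq_target' must lie in (0, 1)")
  if (cut_height_quantile <= 0 || cut_height_quantile >= 1)
    stop("'cut_height_quantile' must lie in (0, 1)")
  structure(list(beta = beta, correlation_kind = "pearson",
                 min_module_size = min_module_size,
                 rsq_target = rsq_target,
                 cut_height_quantile = cut_height_quantile,
                 gap = gap, attach_frac = attach_frac),
            class = "network_params")
}

#' Pearson correlation and soft-thresholded adjacency
#'
#' Computes the probe-probe Pearson correlation across samples and the
#' unsigned soft adjacency `a_ij = |cor_ij|^beta` (i != j). The diagonal
#' is excluded from every connectivity sum downstream.
#'
#' @param expr an [expression_matrix()] with >= 3 samples, no missing
#'   values and no zero-variance probe.
#' @param params a [network_params()].
#' @return a `network_model`: list with `probe_ids`, `correlation`,
#'   `adjacency`, `tom` (`NULL` until [topological_overlap()]), `params`.
#' @export
correlation_adjacency <- function(expr, params = network_params()) {
  x <- expr$values
  if (ncol(x) < 3) stop("need at least 3 samples")
  if (any(is.na(x))) stop("missing values present; impute first")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance probe(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  cc <- stats::cor(t(x))
  adj <- abs(cc)^params$beta
  diag(adj) <- 0
  structure(list(probe_ids = rownames(x), correlation = cc,
                 adjacency = adj, tom = NULL, params = params),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d probes, beta = %g, TOM %s\n",
              length(x$probe_ids), x$params$beta,
              if (is.null(x$tom)) "not computed" else "computed"))
  invisible(x)
}

# scale-free topology fit index of a connectivity vector: equal-width
# binning of k, then R^2 of log10(frequency) on log10(mean k), signed
# negative when the slope is positive
scale_free_fit <- function(k, n_bins = 10) {
  if (stats::sd(k) == 0 || any(k < 0)) return(NA_real_)
  if (diff(range(k)) < 1e-9 * max(abs(k), 1)) return(NA_real_)
  bins <- tryCatch(cut(k, breaks = n_bins),
                   error = function(e) NULL)
  if (is.null(bins)) return(NA_real_)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & !is.na(pk) & dk > 0
  if (sum(ok) < 3) return(NA_real_)
  lx <- log10(dk[ok]); ly <- log10(pk[ok])
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes the connectivity
#' `k_i = sum_{j != i} |cor_ij|^beta`, bins k into 10 equal-width bins
#' and regresses log10 bin frequency on log10 mean bin connectivity; the
#' fit index is the R^2, signed negative when the slope is positive
#' (heavier-than-power-law tails). Returns the smallest beta whose index
#' reaches `rsq_target`; if none does, the beta of maximal index, with a
#' warning.
#'
#' @param expr an [expression_matrix()] with >= 30 probes.
#' @param candidate_betas integer powers to scan (default 1..20).
#' @param rsq_target fit-index target (default 0.85).
#' @return list with `beta` and `fit_table` (data.frame: beta,
#'   fit_index, mean_k, max_k).
#' @export
pick_soft_threshold <- function(expr, candidate_betas = 1:20,
                                rsq_target = 0.85) {
  x <- expr$values
  if (nrow(x) < 30) stop("need at least 30 probes for degree binning")
  if (any(is.na(x))) stop("missing values present; impute first")
  ac <- abs(stats::cor(t(x)))
  diag(ac) <- 0
  tab <- data.frame(beta = candidate_betas, fit_index = NA_real_,
                    mean_k = NA_real_, max_k = NA_real_)
  for (i in seq_along(candidate_betas)) {
    k <- rowSums(ac^candidate_betas[i])
    tab$fit_index[i] <- scale_free_fit(k)
    tab$mean_k[i] <- mean(k)
    tab$max_k[i] <- max(k)
  }
  if (all(is.na(tab$fit_index))) {
    warning("scale-free fit undefined for every candidate beta ",
            "(degenerate connectivity); returning smallest beta")
    return(list(beta = candidate_betas[1], fit_table = tab))
  }
  hit <- which(!is.na(tab$fit_index) & tab$fit_index >= rsq_target)
  if (length(hit)) {
    beta <- candidate_betas[hit[1]]
  } else {
    beta <- candidate_betas[which.max(tab$fit_index)]
    warning("no candidate beta reached fit index ", rsq_target,
            "; using beta = ", beta, " (maximal index ",
            signif(max(tab$fit_index, na.rm = TRUE), 3), ")")
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' Transforms the adjacency into the topological overlap similarity
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `TOM_ii = 1`, so two probes are similar when they are strongly
#' connected and share neighbours. Computed with matrix products; agrees
#' with the triple-loop definition to numerical precision.
#'
#' @param model a `network_model` from [correlation_adjacency()].
#' @return the model with `tom` filled (symmetric, entries in \[0, 1\]).
#' @export
topological_overlap <- function(model) {
  a <- model$adjacency
  l <- a %*% a            # diag(a) = 0, so l_ij = sum_u a_iu a_uj
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  model$tom <- tom
  model
}

# merge-tree helpers over stats::hclust structures -------------------------

hclust_leaves <- function(merge, node) {
  if (node < 0) return(-node)
  out <- integer(0); stack <- node
  while (length(stack)) {
    m <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (m < 0) out <- c(out, -m)
    else stack <- c(stack, merge[m, 1], merge[m, 2])
  }
  out
}

# maximal subnodes (merges or leaves) of `node` with height < h
hclust_components <- function(merge, height, node, h) {
  comps <- list(); stack <- node
  while (length(stack)) {
    m <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (m < 0 || height[m] < h) comps[[length(comps) + 1L]] <- m
    else stack <- c(stack, merge[m, 1], merge[m, 2])
  }
  comps
}

#' Module detection by adaptive cutting of the TOM dendrogram
#'
#' Clusters probes by average-linkage hierarchical clustering of the
#' dissimilarity `1 - TOM` and cuts the dendrogram adaptively, in three
#' deterministic phases:
#' \enumerate{
#'   \item \emph{Static scan}: every cut height up to the
#'     `cut_height_quantile` of merge heights is scored by the number of
#'     clusters of at least `min_module_size` probes; the scan keeps the
#'     cut maximizing that count, ties going to the tightest (lowest)
#'     such cut. This isolates module cores from the near-ceiling ladder
#'     of background-probe merges.
#'   \item \emph{Stem splitting}: a kept branch is split recursively
#'     whenever its top join sits at least `gap` above both child
#'     branches and both children hold `min_module_size` probes
#'     (two tight modules joined by a long stem).
#'   \item \emph{Re-attachment}: each unassigned probe joins the module
#'     core with the largest ratio of mean TOM (probe to core) over the
#'     core's median internal TOM, provided that ratio reaches
#'     `attach_frac`; otherwise it stays unassigned (label 0).
#' }
#' Clusters below `min_module_size` are discarded to label 0 and labels
#' are renumbered by decreasing module size. The procedure involves no
#' randomness: identical input gives identical labels.
#'
#' @param model a `network_model` with `tom` filled.
#' @param params a [network_params()]; defaults to the model's.
#' @return named integer vector of module labels (0 = unassigned),
#'   in probe order.
#' @export
cluster_and_cut <- function(model, params = model$params) {
  if (is.null(model$tom)) stop("run topological_overlap() first")
  tom <- model$tom
  n <- nrow(tom)
  if (params$min_module_size > n) {
    warning("min_module_size exceeds the number of probes; ",
            "all probes unassigned")
    return(stats::setNames(integer(n), model$probe_ids))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  H <- hc$height; M <- hc$merge
  # phase 1: scan cut heights for the maximal number of large clusters
  h_max <- as.numeric(stats::quantile(H, params$cut_height_quantile))
  cand <- sort(unique(H))
  mids <- c((cand[-1] + cand[-length(cand)]) / 2,
            max(H) + .Machine$double.eps)
  mids <- mids[mids <= h_max + .Machine$double.eps]
  if (!length(mids)) mids <- h_max
  best_h <- mids[1]; best_n <- -1L
  for (h in mids) {
    nn <- sum(table(stats::cutree(hc, h = h)) >= params$min_module_size)
    if (nn > best_n) { best_n <- nn; best_h <- h }
  }
  # phase 2: recursive stem split inside each kept branch
  parent <- integer(n - 1)
  for (i in seq_len(n - 1))
    for (j in 1:2) if (M[i, j] > 0) parent[M[i, j]] <- i
  top_merges <- Filter(function(i) parent[i] == 0 || H[parent[i]] > best_h,
                       which(H <= best_h))
  in_merge <- unique(unlist(lapply(top_merges,
                                   function(m) hclust_leaves(M, m))))
  singletons <- setdiff(seq_len(n), in_merge)
  clusters <- list()
  height_of <- function(m) if (m < 0) 0 else H[m]
  for (root in top_merges) {
    stack <- root
    while (length(stack)) {
      m <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (m < 0) { clusters[[length(clusters) + 1L]] <- -m; next }
      c1 <- M[m, 1]; c2 <- M[m, 2]
      l1 <- hclust_leaves(M, c1); l2 <- hclust_leaves(M, c2)
      if (length(l1) >= params$min_module_size &&
          length(l2) >= params$min_module_size &&
          H[m] - max(height_of(c1), height_of(c2)) >= params$gap) {
        stack <- c(stack, c1, c2)
      } else {
        clusters[[length(clusters) + 1L]] <- c(l1, l2)
      }
    }
  }
  lab <- integer(n)
  ci <- 0L
  for (cl in clusters)
    if (length(cl) >= params$min_module_size) { ci <- ci + 1L; lab[cl] <- ci }
  # phase 3: TOM-based re-attachment of unassigned probes
  if (ci > 0) {
    cores <- lapply(seq_len(ci), function(k) which(lab == k))
    core_tom <- vapply(cores, function(cc) {
      tt <- tom[cc, cc]; stats::median(tt[upper.tri(tt)])
    }, 0)
    for (g in which(lab == 0L)) {
      ratio <- vapply(seq_len(ci), function(k)
        mean(tom[g, cores[[k]]]) / core_tom[k], 0)
      if (max(ratio) >= params$attach_frac) lab[g] <- which.max(ratio)
    }
    # renumber by decreasing size (ties by original label)
    sz <- table(lab[lab > 0])
    ord <- order(-as.integer(sz), as.integer(names(sz)))
    remap <- integer(ci)
    remap[as.integer(names(sz))[ord]] <- seq_along(ord)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  stats::setNames(lab, model$probe_ids)
}

#' Connectivity decomposition
#'
#' Per probe: total soft connectivity `kTotal = sum_{j != i} a_ij`, its
#' within-module part `kWithin` (same nonzero module) and the remainder
#' `kOut = kTotal - kWithin`; unassigned probes have `kWithin = 0`.
#'
#' @param model a `network_model` (adjacency filled).
#' @param assignment module labels from [cluster_and_cut()].
#' @return data.frame `probe_id`, `module`, `kTotal`, `kWithin`, `kOut`.
#' @export
connectivity <- function(model, assignment) {
  a <- model$adjacency
  k_total <- rowSums(a)
  k_within <- numeric(length(k_total))
  for (m in setdiff(unique(assignment), 0L)) {
    idx <- which(assignment == m)
    k_within[idx] <- rowSums(a[idx, idx, drop = FALSE])
  }
  data.frame(probe_id = model$probe_ids,
             module = as.integer(assignment),
             kTotal = k_total, kWithin = k_within,
             kOut = k_total - k_within,
             stringsAsFactors = FALSE, row.names = NULL)
}
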