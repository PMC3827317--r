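#' Fit a weighted co-expression network model
#'
#' The package's central fitting function. From a probe-by-sample
#' expression matrix it builds the unsigned weighted network (Pearson
#' correlation soft-thresholded to adjacency `|cor|^beta`), transforms
#' it to topological overlap, detects modules by adaptive cutting of
#' the average-linkage TOM dendrogram, and computes eigengenes, module
#' membership (kME) and connectivity. When `beta = NULL` the power is
#' chosen by the scale-free topology criterion ([pick_soft_threshold()]).
#'
#' @param expr an [expression_matrix()] (glog2 scale, no missing
#'   values, no zero-variance probes) or a plain numeric matrix.
#' @param beta soft-threshold power; `NULL` to select automatically.
#' @param params a [network_params()]; its `beta` is overridden by the
#'   `beta` argument or the automatic choice.
#' @return an object of class `wcna`: list with `network` (the
#'   `network_model`, TOM filled), `assignment`, `eigengenes`, `kme`,
#'   `connectivity`, `beta`, `beta_fit` (the soft-threshold scan table,
#'   or `NULL` when `beta` was given), `n_modules`, `call`.
#' @seealso [module_significance()], [hub_genes()],
#'   [export_cytoscape()] for downstream analysis of a fit.
#' @export
#' @examples
#' sim <- simulate_endotoxemia(seed = 1)
#' fit <- wcna(sim$expr, beta = 6)
#' fit
#' table(truth = sim$truth$module_of_probe, found = fit$assignment)
wcna <- function(expr, beta = NULL, params = network_params()) {
  cl <- match.call()
  if (is.matrix(expr)) expr <- expression_matrix(expr)
  beta_fit <- NULL
  if (is.null(beta)) {
    pick <- pick_soft_threshold(expr, rsq_target = params$rsq_target)
    beta <- pick$beta
    beta_fit <- pick$fit_table
  }
  params$beta <- beta
  net <- correlation_adjacency(expr, params)
  net <- topological_overlap(net)
  assignment <- cluster_and_cut(net)
  n_mod <- length(setdiff(unique(assignment), 0L))
  eig <- if (n_mod > 0) module_eigengenes(expr, assignment) else NULL
  kme <- if (n_mod > 0) module_membership(expr, eig) else NULL
  conn <- connectivity(net, assignment)
  x <- expr$values
  z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  structure(list(network = net, assignment = assignment,
                 eigengenes = eig, kme = kme, connectivity = conn,
                 standardized = z,
                 beta = beta, beta_fit = beta_fit, n_modules = n_mod,
                 call = cl),
            class = "wcna")
}

#' @export
print.wcna <- function(x, ...) {
  cat("Weighted co-expression network fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d probes, beta = %g%s\n", length(x$assignment), x$beta,
              if (is.null(x$beta_fit)) "" else " (scale-free criterion)"))
  sz <- table(x$assignment[x$assignment > 0])
  cat(sprintf("%d module(s), %d unassigned probe(s)\n", x$n_modules,
              sum(x$assignment == 0)))
  if (length(sz))
    cat("module sizes:", paste(as.integer(sz), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.wcna <- function(object, ...) {
  sz <- as.integer(table(object$assignment[object$assignment > 0]))
  out <- list(n_probes = length(object$assignment),
              beta = object$beta,
              n_modules = object$n_modules,
              module_sizes = sz,
              n_unassigned = sum(object$assignment == 0),
              variance_explained =
                if (is.null(object$eigengenes)) numeric(0)
                else object$eigengenes$variance_explained,
              mean_kTotal = mean(object$connectivity$kTotal))
  class(out) <- "summary.wcna"
  out
}

#' @export
print.summary.wcna <- function(x, ...) {
  cat(sprintf("wcna fit: %d probes, beta = %g\n", x$n_probes, x$beta))
  cat(sprintf("modules: %d (sizes %s), unassigned: %d\n", x$n_modules,
              paste(x$module_sizes, collapse = ", "), x$n_unassigned))
  if (length(x$variance_explained))
    cat("eigengene variance explained:",
        paste(sprintf("%.2f", x$variance_explained), collapse = ", "),
        "\n")
  cat(sprintf("mean total connectivity: %.2f\n", x$mean_kTotal))
  invisible(x)
}

#' @export
#' @rdname wcna
#' @param object,x a `wcna` fit.
#' @param ... unused.
#' @details `coef()` returns the kME matrix (each probe's loading on
#'   each module eigengene); `fitted()` the rank-M reconstruction of
#'   the standardized expression from the eigengenes; `residuals()` the
#'   corresponding residual matrix.
coef.wcna <- function(object, ...) object$kme

# least-squares projection of the rows of z on the row space of e
project_rows <- function(z, e) {
  z %*% t(e) %*% solve(e %*% t(e)) %*% e
}

#' @export
fitted.wcna <- function(object, ...) {
  if (is.null(object$eigengenes))
    stop("no modules were found; nothing fitted")
  project_rows(object$standardized, object$eigengenes$eigengenes)
}

#' @export
residuals.wcna <- function(object, ...) {
  object$standardized - fitted(object)
}

#' @export
#' @rdname wcna
#' @param newdata an [expression_matrix()] (or matrix) of new probes
#'   over the same samples as the fit.
#' @param min_kme minimum |kME| for a new probe to be assigned
#'   (default 0.5); below it the probe gets module 0.
#' @details `predict()` assigns new probes to the fitted modules by
#'   maximal |kME| against the existing eigengenes.
predict.wcna <- function(object, newdata, min_kme = 0.5, ...) {
  if (is.null(object$eigengenes))
    stop("no modules were found; nothing to predict")
  x <- if (is.matrix(newdata)) newdata else newdata$values
  if (!identical(colnames(x), object$eigengenes$sample_ids))
    stop("newdata must cover the fit's samples in the same order")
  kme <- stats::cor(t(x), t(object$eigengenes$eigengenes))
  best <- max.col(abs(kme), ties.method = "first")
  module <- object$eigengenes$module_ids[best]
  module[abs(kme)[cbind(seq_len(nrow(kme)), best)] < min_kme] <- 0L
  data.frame(probe_id = rownames(x), module = module,
             kme = kme[cbind(seq_len(nrow(kme)), best)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
plot.wcna <- function(x, ...) {
  hc <- stats::hclust(stats::as.dist(1 - x$network$tom),
                      method = "average")
  graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  plot(hc, labels = FALSE, hang = -1, main = "TOM dendrogram",
       xlab = "", sub = "", ...)
  ord <- x$assignment[hc$order]
  graphics::par(mar = c(3, 4, 0.5, 1))
  graphics::image(matrix(as.integer(ord), ncol = 1),
                  col = c("grey85", grDevices::hcl.colors(
                    max(1, max(ord)), "Dark 3")),
                  axes = FALSE, ylab = "module")
  invisible(x)
}

#' @export
#' @rdname wcna
#' @param nsim,seed passed as in [stats::simulate()]: number of
#'   synthetic datasets and RNG seed.
#' @details `simulate()` draws synthetic datasets whose planted module
#'   structure matches the fit (module count and sizes), via
#'   [simulate_endotoxemia()]; useful for parametric-bootstrap checks
#'   of the module detection.
simulate.wcna <- function(object, nsim = 1, seed = 1, ...) {
  sz <- as.integer(table(object$assignment[object$assignment > 0]))
  gpm <- if (length(sz)) max(2L, as.integer(round(mean(sz)))) else 50L
  nm <- max(1L, object$n_modules)
  lapply(seq_len(nsim), function(i)
    simulate_endotoxemia(n_modules = nm, genes_per_module = gpm,
                         n_background = sum(object$assignment == 0),
                         lps_effects = rep(1, nm),
                         interaction_effects = rep(0, nm),
                         seed = seed + i - 1L))
}
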