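#' Filter non-expressed probes by detection p-value
#'
#' Keeps probes whose detection p-value falls below `p_threshold` in at
#' least `min_samples` samples; probe order is preserved. On the study's
#' array platform this filter (threshold 0.05, detected anywhere) reduces
#' the full probe complement to the expressed subset.
#'
#' @param expr an [expression_matrix()] with detection p-values.
#' @param p_threshold detection p-value cutoff (default 0.05).
#' @param min_samples minimum number of samples in which a probe must be
#'   detected (default 1, the most permissive reading).
#' @return the filtered [expression_matrix()].
#' @export
filter_detected <- function(expr, p_threshold = 0.05, min_samples = 1) {
  if (is.null(expr$detection_p))
    stop("expression matrix carries no detection p-values")
  n_det <- rowSums(expr$detection_p < p_threshold, na.rm = TRUE)
  keep <- n_det >= min_samples
  expression_matrix(expr$values[keep, , drop = FALSE],
                    detection_p = expr$detection_p[keep, , drop = FALSE],
                    scale = expr$scale)
}

#' K-nearest-neighbour imputation of missing cells
#'
#' Each missing cell (g, s) is replaced by the inverse-distance-weighted
#' mean of the `k` nearest probes that are observed at sample s. Distance
#' between two probes is the Euclidean distance over the columns observed
#' in both, scaled by the number of shared columns
#' (`sqrt(mean((x - y)^2))`); ties are broken by probe order. Probes at
#' zero distance (exact duplicates) take the cell's value directly.
#'
#' @param expr an [expression_matrix()].
#' @param k number of neighbours (default 15, the study's setting).
#' @return the imputed [expression_matrix()] with no missing cells;
#'   observed values are untouched. Applying the function twice is a
#'   no-op.
#' @export
knn_impute <- function(expr, k = 15) {
  if (k < 1) stop("'k' must be at least 1")
  x <- expr$values
  miss <- is.na(x)
  if (!any(miss)) return(expr)
  all_gone <- rowSums(!miss) == 0
  if (any(all_gone))
    stop("probe(s) with all values missing: ",
         paste(rownames(x)[all_gone], collapse = ", "))
  todo <- which(rowSums(miss) > 0)
  for (g in todo) {
    obs_g <- !miss[g, ]
    # candidate neighbours share >= 1 observed column with g
    shared <- (!t(miss)) & obs_g          # samples x probes
    n_shared <- colSums(shared)
    d2 <- colMeans((t(x) - x[g, ])^2, na.rm = TRUE)  # mean over shared cols
    d <- sqrt(d2)
    for (s in which(miss[g, ])) {
      elig <- which(!miss[, s] & n_shared > 0 & seq_len(nrow(x)) != g)
      if (!length(elig))
        stop("no eligible neighbour for probe ", rownames(x)[g],
             " at sample ", colnames(x)[s])
      if (length(elig) < k)
        warning("fewer than k = ", k, " eligible neighbours for probe ",
                rownames(x)[g], " at sample ", colnames(x)[s],
                "; using all ", length(elig))
      ord <- elig[order(d[elig], elig)]
      nn <- ord[seq_len(min(k, length(ord)))]
      dn <- d[nn]
      if (any(dn == 0)) {
        x[g, s] <- mean(x[nn[dn == 0], s])
      } else {
        w <- 1 / dn
        x[g, s] <- sum(w * x[nn, s]) / sum(w)
      }
    }
  }
  expression_matrix(x, detection_p = expr$detection_p, scale = expr$scale)
}

#' Generalized log2
#'
#' `glog2(x, c) = log2((x + sqrt(x^2 + c^2)) / 2)`: strictly increasing,
#' defined for all real x, variance-stabilizing for intensities with
#' additive-plus-multiplicative noise; equals `log2(x)` when `c = 0` and
#' `x > 0`, and approaches `log2(x)` as `x/c` grows.
#'
#' @param x numeric.
#' @param c non-negative glog parameter.
#' @return numeric of the same shape as `x`.
#' @export
#' @examples
#' glog2(8, 0)   # 3
#' glog2(3, 4)   # log2((3 + 5)/2) = 2
glog2 <- function(x, c) {
  if (any(c < 0)) stop("'c' must be non-negative")
  log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Variance-stabilizing normalization of raw intensities
#'
#' Calibrates each array against a median pseudo-array with a per-sample
#' affine map and transforms onto the glog2 scale, the model class of
#' variance-stabilizing normalization for microarray intensities. The
#' affine parameters are estimated robustly: a trimmed regression on the
#' central half of rank-matched quantiles seeds per-sample gain and
#' offset, which are then refined by iterating gain = median of ratios
#' over central-intensity probes and offset = median residual over
#' low-intensity probes (heavy-tailed high-intensity scatter makes plain
#' least squares unreliable here). The glog parameter `c` is
#' `1.4826 * median |residual|` of the calibrated values over the
#' lowest-quartile-intensity probes; with replicate-identical arrays it
#' is exactly 0 and the transform reduces to `log2`.
#'
#' @param expr an [expression_matrix()] on the raw scale with no missing
#'   values (impute first).
#' @param iters refinement iterations (default 3).
#' @return list with `expr` (the normalized [expression_matrix()],
#'   glog2 scale) and `fit` (a `normalization_fit`: per-sample `offset`,
#'   `scale`, and glog parameter `c`).
#' @export
vsn_normalize <- function(expr, iters = 3) {
  x <- expr$values
  if (any(is.na(x)))
    stop("missing values present; run knn_impute() first")
  const <- apply(x, 2, stats::sd) == 0
  if (any(const))
    stop("constant column(s): ",
         paste(colnames(x)[const], collapse = ", "))
  n <- nrow(x); S <- ncol(x)
  ref <- apply(x, 1, stats::median)
  qr <- sort(ref)
  lo <- floor(n * 0.25) + 1L; hi <- ceiling(n * 0.75)
  a <- numeric(S); b <- numeric(S)
  for (s in seq_len(S)) {
    qx <- sort(x[, s])
    cf <- stats::coef(stats::lm(qx[lo:hi] ~ qr[lo:hi]))
    a[s] <- cf[1]; b[s] <- cf[2]
  }
  for (it in seq_len(iters)) {
    cal <- sweep(sweep(x, 2, a, "-"), 2, b, "/")
    target <- apply(cal, 1, stats::median)
    ord <- order(target)
    mid <- ord[(floor(n * 0.25) + 1L):ceiling(n * 0.75)]
    low <- ord[seq_len(max(20L, floor(n * 0.1)))]
    for (s in seq_len(S)) {
      b[s] <- stats::median((x[mid, s] - a[s]) / target[mid])
      a[s] <- stats::median(x[low, s] - b[s] * target[low])
    }
  }
  if (any(b <= 0))
    stop("non-positive estimated gain for sample(s): ",
         paste(colnames(x)[b <= 0], collapse = ", "))
  cal <- sweep(sweep(x, 2, a, "-"), 2, b, "/")
  med <- apply(cal, 1, stats::median)
  resid <- cal - med
  bg <- rank(med, ties.method = "first") <= n * 0.25
  cc <- 1.4826 * stats::median(abs(resid[bg, ]))
  y <- glog2(cal, cc)
  dimnames(y) <- dimnames(x)
  fit <- structure(list(offset = stats::setNames(a, colnames(x)),
                        scale = stats::setNames(b, colnames(x)),
                        c = cc),
                   class = "normalization_fit")
  list(expr = expression_matrix(y, detection_p = expr$detection_p,
                                scale = "glog2"),
       fit = fit)
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("normalization_fit: %d samples, gains %.3g..%.3g, c = %.4g\n",
              length(x$scale), min(x$scale), max(x$scale), x$c))
  invisible(x)
}

#' @rdname vsn_normalize
#' @param fit a `normalization_fit`
#' @param path output TSV path (sample, offset, scale, c)
#' @export
write_normalization_fit <- function(fit, path) {
  utils::write.table(
    data.frame(sample_id = names(fit$scale), offset = fit$offset,
               scale = fit$scale, c = fit$c),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
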