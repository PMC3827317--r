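de_result <- function(df, comparison) {
  attr(df, "comparison") <- comparison
  class(df) <- c("de_result", "data.frame")
  df
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result (%s): %d probes, %d with q < 0.05\n",
              attr(x, "comparison"), nrow(x), sum(x$q < 0.05)))
  invisible(x)
}

#' Paired t statistics and fold changes for the LPS response of one arm
#'
#' For every probe, forms per-subject differences d = y(t4) - y(t0) over
#' the arm's complete pairs and tests mean(d) = 0 with the paired Student
#' t statistic, `t = mean(d) / (sd(d)/sqrt(n))`, df = n - 1, two-sided p.
#' The log2 fold change is `mean(d)` (the data are on the glog2 scale, so
#' a paired difference is a log2 ratio). Zero-variance differences with a
#' nonzero mean give an infinite t and p = 0, with a warning, so the
#' probe count is preserved.
#'
#' @param expr an [expression_matrix()] (glog2 scale, no missing values).
#' @param design a [study_design()].
#' @param arm which arm's pairs to use.
#' @return a `de_result` data.frame: `probe_id`, `log2_fc`, `statistic`,
#'   `statistic_kind`, `df`, `p`, `q` (Benjamini-Hochberg).
#' @export
paired_t_fc <- function(expr, design, arm = c("placebo", "etanercept")) {
  arm <- match.arg(arm)
  pairs <- complete_pairs(design, arm)
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 complete (t0, t4) pairs in the ", arm,
                  " arm")
  x <- expr$values
  missing_samples <- setdiff(c(pairs$t0, pairs$t4), colnames(x))
  if (length(missing_samples))
    stop("design sample(s) absent from expression matrix: ",
         paste(missing_samples, collapse = ", "))
  d <- x[, pairs$t4, drop = FALSE] - x[, pairs$t0, drop = FALSE]
  m <- rowMeans(d)
  s <- apply(d, 1, stats::sd)
  tstat <- m / (s / sqrt(n))
  zero_var <- s == 0
  tstat[zero_var & m == 0] <- 0
  degenerate <- zero_var & m != 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " probe(s) with zero-variance nonzero differences; ",
            "t set to +/-Inf, p to 0")
    tstat[degenerate] <- sign(m[degenerate]) * Inf
  }
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[zero_var & m == 0] <- 1
  p[degenerate] <- 0
  # p.adjust directly: degenerate probes may carry p = 0, which the
  # user-facing bh_fdr() rejects by contract
  de_result(data.frame(probe_id = rownames(x), log2_fc = m,
                       statistic = tstat, statistic_kind = "paired_t",
                       df = n - 1, p = p, q = stats::p.adjust(p, "BH"),
                       stringsAsFactors = FALSE, row.names = NULL),
            comparison = paste0("lps_", arm))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) (m * p_(j) / j)`, capped at 1 and returned in
#' the input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Volcano classification of differentially expressed probes
#'
#' Flags probes with `q < q_threshold` and an absolute fold change of at
#' least `fold_threshold` (inclusive on the log2 scale:
#' `|log2_fc| >= log2(fold_threshold)`).
#'
#' @param de a `de_result`.
#' @param q_threshold FDR cutoff (default 0.01).
#' @param fold_threshold linear fold-change cutoff, > 1 (default 1.5).
#' @return list with `flags` (data.frame `probe_id`, `flagged`, `direction`)
#'   and `n_flagged`.
#' @export
volcano_classify <- function(de, q_threshold = 0.01, fold_threshold = 1.5) {
  if (fold_threshold <= 1) stop("'fold_threshold' must exceed 1")
  lfc <- log2(fold_threshold)
  flagged <- de$q < q_threshold & abs(de$log2_fc) >= lfc
  direction <- ifelse(!flagged, "none",
                      ifelse(de$log2_fc > 0, "up", "down"))
  list(flags = data.frame(probe_id = de$probe_id, flagged = flagged,
                          direction = direction, stringsAsFactors = FALSE),
       n_flagged = sum(flagged))
}

#' Nested-model ANOVA for treatment-responsive probes
#'
#' Per probe, compares a full linear model of the post-LPS value on the
#' subject's own baseline plus an arm indicator,
#' `y_t4 = b0 + b1 * y_t0 + b2 * 1[etanercept]`, against the reduced
#' model without the arm term, across all subjects with complete pairs in
#' both arms. The extra-sum-of-squares F statistic
#' `F = (RSS_red - RSS_full) / (RSS_full / (n - 3))` with df (1, n - 3)
#' equals the squared t of the arm coefficient; probes whose q-value
#' passes a cutoff are the treatment-responsive set.
#'
#' @param expr an [expression_matrix()] (glog2 scale, no missing values).
#' @param design a [study_design()] with complete pairs in both arms.
#' @return a `de_result` data.frame with `statistic_kind = "anova_f"`;
#'   `log2_fc` is the arm coefficient `b2` (etanercept minus placebo
#'   post-LPS shift at fixed baseline).
#' @export
nested_model_ftest <- function(expr, design) {
  pp <- complete_pairs(design, "placebo")
  pe <- complete_pairs(design, "etanercept")
  if (nrow(pp) == 0 || nrow(pe) == 0)
    stop("both arms must contribute complete pairs")
  pairs <- rbind(pp, pe)
  n <- nrow(pairs)
  if (n <= 3) stop("need more than 3 subjects with complete pairs")
  x <- expr$values
  y0 <- t(x[, pairs$t0, drop = FALSE])
  y4 <- t(x[, pairs$t4, drop = FALSE])
  etan <- as.numeric(seq_len(n) > nrow(pp))
  G <- nrow(x)
  fstat <- beta2 <- numeric(G)
  for (g in seq_len(G)) {
    Xf <- cbind(1, y0[, g], etan)
    fit_full <- stats::.lm.fit(Xf, y4[, g])
    fit_red <- stats::.lm.fit(Xf[, 1:2, drop = FALSE], y4[, g])
    rss_full <- sum(fit_full$residuals^2)
    rss_red <- sum(fit_red$residuals^2)
    if (fit_full$rank < 3)
      stop("collinear design for probe ", rownames(x)[g],
           " (single arm or constant baseline)")
    extra <- max(0, rss_red - rss_full)
    # noiseless probes: both models fit exactly -> F = 0 by convention;
    # an exact full fit with a real arm effect -> infinite F. "Exact" is
    # judged relative to the response scale, not against literal 0.
    zero_tol <- 1e-12 * max(1, sum(y4[, g]^2))
    fstat[g] <- if (rss_full <= zero_tol) {
      if (extra <= zero_tol) 0 else Inf
    } else extra / (rss_full / (n - 3))
    beta2[g] <- fit_full$coefficients[3]
  }
  p <- stats::pf(fstat, 1, n - 3, lower.tail = FALSE)
  de_result(data.frame(probe_id = rownames(x), log2_fc = beta2,
                       statistic = fstat, statistic_kind = "anova_f",
                       df = n - 3, p = p, q = stats::p.adjust(p, "BH"),
                       stringsAsFactors = FALSE, row.names = NULL),
            comparison = "tnf_responsive_anova")
}

#' @rdname paired_t_fc
#' @param de a `de_result` to write
#' @param path output TSV path
#' @export
write_de_result <- function(de, path) {
  out <- as.data.frame(de)
  out$comparison <- attr(de, "comparison")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
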