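#' Simulate a paired two-arm expression study with planted modules
#'
#' Generates a probe-by-sample matrix from a latent factor model that
#' mimics an endotoxemia challenge study: every subject contributes a
#' baseline (t0) and a post-LPS (t4) array, subjects split into a placebo
#' and an etanercept arm, and each planted module m follows one latent
#' factor
#' \deqn{e_m(s) = z_m(subject) + \delta_m 1[t4] + \gamma_m 1[t4 \wedge etanercept]}
#' with subject random intercepts \eqn{z_m \sim N(0,1)}, an LPS main
#' effect \eqn{\delta_m} and an arm-by-LPS interaction \eqn{\gamma_m}.
#' Probe g in module m is \eqn{x_g = \mu_g + \lambda_g e_m + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}; background probes have
#' \eqn{\lambda = 0}. The first probe of each module is its designated
#' hub, planted at `hub_loading`, well above the peripheral loadings so
#' that hub identity is statistically identifiable at the default cohort
#' size; peripheral loadings are drawn uniformly from `loading_range`.
#'
#' With `raw_layer = TRUE` the returned matrix is pushed through a
#' scanner-like layer `raw = a_s + b_s * 2^x * exp(eta)`,
#' `eta ~ N(0, tau^2)`, with per-array offsets `a_s` and gains `b_s`,
#' and the clean glog2-scale matrix is kept in the truth record.
#'
#' @param n_modules number of planted modules.
#' @param genes_per_module probes per module.
#' @param n_background unassigned background probes.
#' @param subjects_per_arm paired subjects per arm.
#' @param lps_effects numeric, length `n_modules`: \eqn{\delta_m}.
#' @param interaction_effects numeric, length `n_modules`: \eqn{\gamma_m}.
#' @param loading_range range of peripheral loadings.
#' @param hub_loading loading of the planted hub probe of each module.
#' @param noise_sd residual standard deviation \eqn{\sigma}.
#' @param missing_rate fraction of cells set missing at random.
#' @param raw_layer return raw intensities instead of glog2 values.
#' @param baseline_range range of per-probe baseline means \eqn{\mu_g}
#'   (glog2 scale).
#' @param offset_range,gain_range,tau raw-layer parameters.
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return list with elements `expr` ([expression_matrix()]), `design`
#'   ([study_design()]) and `truth` (class `synthetic_truth`): module
#'   labels (`0` = background), loadings, hub probes, latent factors,
#'   effect sizes, raw-layer parameters and, when `raw_layer = TRUE`,
#'   the clean glog2 matrix `expr_clean`.
#' @export
#' @examples
#' sim <- simulate_endotoxemia(seed = 1)
#' table(sim$truth$module_of_probe)
simulate_endotoxemia <- function(n_modules = 3,
                                 genes_per_module = 50,
                                 n_background = 50,
                                 subjects_per_arm = 8,
                                 lps_effects = c(1.0, -0.8, 0.6),
                                 interaction_effects = c(1.3, -1.0, 0),
                                 loading_range = c(0.75, 0.95),
                                 hub_loading = 2,
                                 noise_sd = 0.5,
                                 missing_rate = 0,
                                 raw_layer = FALSE,
                                 baseline_range = c(6, 12),
                                 offset_range = c(10, 50),
                                 gain_range = c(0.5, 2),
                                 tau = 0.05,
                                 seed = 1) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (missing_rate < 0 || missing_rate > 1)
    stop("'missing_rate' must lie in [0, 1]")
  if (n_modules > 0 && (length(lps_effects) != n_modules ||
                        length(interaction_effects) != n_modules))
    stop("effect vectors must have length n_modules")
  if (min(n_modules, genes_per_module, n_background, subjects_per_arm) < 0)
    stop("counts must be non-negative")
  set.seed(as.integer(seed))

  n_sub <- 2L * subjects_per_arm
  subject_id <- sprintf("S%02d", seq_len(n_sub))
  subject_arm <- rep(c("placebo", "etanercept"), each = subjects_per_arm)
  design <- data.frame(
    sample_id = paste(rep(subject_id, each = 2), c("t0", "t4"), sep = "_"),
    subject_id = rep(subject_id, each = 2),
    arm = rep(subject_arm, each = 2),
    timepoint = rep(c("t0", "t4"), times = n_sub),
    stringsAsFactors = FALSE)
  design <- study_design(design)
  n_samp <- nrow(design)
  is_t4 <- design$timepoint == "t4"
  is_etan <- design$arm == "etanercept"
  subj_idx <- match(design$subject_id, subject_id)

  n_probe <- n_modules * genes_per_module + n_background
  module <- c(rep(seq_len(n_modules), each = genes_per_module),
              rep(0L, n_background))
  probe_id <- c(if (n_modules > 0)
                  sprintf("MOD%d_%03d", module[module > 0],
                          sequence(rep(genes_per_module, n_modules))),
                if (n_background > 0) sprintf("BG_%03d", seq_len(n_background)))

  loadings <- numeric(n_probe)
  hub_probes <- character(0)
  for (m in seq_len(n_modules)) {
    idx <- which(module == m)
    loadings[idx] <- stats::runif(length(idx), loading_range[1],
                                  loading_range[2])
    loadings[idx[1]] <- hub_loading
    hub_probes <- c(hub_probes, probe_id[idx[1]])
  }

  factors <- matrix(0, nrow = max(n_modules, 1), ncol = n_samp,
                    dimnames = list(NULL, design$sample_id))
  for (m in seq_len(n_modules)) {
    z <- stats::rnorm(n_sub)
    factors[m, ] <- z[subj_idx] + lps_effects[m] * is_t4 +
      interaction_effects[m] * (is_t4 & is_etan)
  }

  mu <- stats::runif(n_probe, baseline_range[1], baseline_range[2])
  x <- matrix(stats::rnorm(n_probe * n_samp, sd = noise_sd),
              n_probe, n_samp) + mu
  for (g in seq_len(n_probe))
    if (module[g] > 0) x[g, ] <- x[g, ] + loadings[g] * factors[module[g], ]
  dimnames(x) <- list(probe_id, design$sample_id)

  offsets <- gains <- NULL
  expr_clean <- NULL
  if (raw_layer) {
    offsets <- stats::runif(n_samp, offset_range[1], offset_range[2])
    gains <- stats::runif(n_samp, gain_range[1], gain_range[2])
    names(offsets) <- names(gains) <- design$sample_id
    eta <- matrix(stats::rnorm(n_probe * n_samp, sd = tau), n_probe, n_samp)
    expr_clean <- x
    x <- sweep(sweep(2^x * exp(eta), 2, gains, "*"), 2, offsets, "+")
    dimnames(x) <- dimnames(expr_clean)
  }

  if (missing_rate > 0) {
    drop <- stats::runif(length(x)) < missing_rate
    x[drop] <- NA_real_
  }

  truth <- structure(list(
    module_of_probe = stats::setNames(module, probe_id),
    loadings = stats::setNames(loadings, probe_id),
    hub_probes = hub_probes,
    latent_factors = if (n_modules > 0) factors[seq_len(n_modules), ,
                                                drop = FALSE] else factors[0, , drop = FALSE],
    lps_effect = lps_effects,
    interaction_effect = interaction_effects,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    offsets = offsets, gains = gains, tau = if (raw_layer) tau else NULL,
    expr_clean = expr_clean,
    seed = as.integer(seed)), class = "synthetic_truth")

  list(expr = expression_matrix(x, scale = if (raw_layer) "raw" else "glog2"),
       design = design,
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d probes, %d module(s), seed %d\n",
              length(x$module_of_probe), length(x$lps_effect), x$seed))
  invisible(x)
}

#' Write a simulated dataset as the package's standard TSV files
#'
#' Writes `expression.tsv`, `design.tsv` and `truth.tsv`
#' (probe, module, loading) into `dir`.
#'
#' @param sim result of [simulate_endotoxemia()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$expr, file.path(dir, "expression.tsv"))
  write_study_design(sim$design, file.path(dir, "design.tsv"))
  utils::write.table(
    data.frame(probe_id = names(sim$truth$module_of_probe),
               module = sim$truth$module_of_probe,
               loading = sim$truth$loadings),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return numeric in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  sum_nij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_nij - expected) / denom
}
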