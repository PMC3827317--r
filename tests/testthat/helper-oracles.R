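# Independent reference implementations used as oracles in the tests.
# These deliberately use the slowest, most literal formulation of each
# definition so that agreement with the package is meaningful.

`%||%` <- function(a, b) if (is.null(a)) b else a

# triple-loop topological overlap:
# TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# O(m^2) Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[ord[j]] / j)
    q[ord[i]] <- min(1, best)
  }
  q
}

# random symmetric adjacency with zero diagonal, entries in [0, 1]
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# toy expression matrix with distinct, non-degenerate probes
toy_expr <- function(n_probe = 10, n_sample = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_probe * n_sample), n_probe, n_sample,
              dimnames = list(sprintf("P%02d", seq_len(n_probe)),
                              sprintf("S%02d", seq_len(n_sample))))
  expression_matrix(x)
}

# minimal valid paired two-arm design, n subjects per arm
toy_design <- function(subjects_per_arm = 4) {
  n <- 2 * subjects_per_arm
  subj <- sprintf("S%02d", seq_len(n))
  study_design(data.frame(
    sample_id = paste(rep(subj, each = 2), c("t0", "t4"), sep = "_"),
    subject_id = rep(subj, each = 2),
    arm = rep(c("placebo", "etanercept"), each = 2 * subjects_per_arm),
    timepoint = rep(c("t0", "t4"), n),
    stringsAsFactors = FALSE))
}
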