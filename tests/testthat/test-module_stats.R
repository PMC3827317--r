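test_that("module of identical probes: eigengene is the common profile, VE = 1", {
  set.seed(29)
  s <- stats::rnorm(8)
  x <- matrix(0, 4, 8, dimnames = list(paste0("p", 1:4), paste0("s", 1:8)))
  for (g in 1:4) x[g, ] <- g * s + g     # same shape, different offset/scale
  asg <- stats::setNames(rep(1L, 4), rownames(x))
  eg <- module_eigengenes(expression_matrix(x), asg)
  e <- eg$eigengenes[1, ]
  z <- (s - mean(s)) / stats::sd(s)
  expect_equal(abs(stats::cor(e, z)), 1, tolerance = 1e-12)
  expect_equal(unname(eg$variance_explained), 1, tolerance = 1e-12)
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
})

test_that("sign convention: negating all probes leaves cor(eigengene, mean) >= 0", {
  set.seed(30)
  x <- matrix(stats::rnorm(5 * 10), 5, 10,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:10)))
  asg <- stats::setNames(rep(1L, 5), rownames(x))
  for (mat in list(x, -x)) {
    eg <- module_eigengenes(expression_matrix(mat), asg)
    zm <- (mat - rowMeans(mat)) / apply(mat, 1, stats::sd)
    expect_gte(stats::cor(eg$eigengenes[1, ], colMeans(zm)), 0)
  }
})

test_that("rank-1 factor model with sigma = 0.3 recovers the factor", {
  sim <- simulate_endotoxemia(n_modules = 1, genes_per_module = 50,
                              n_background = 0, lps_effects = 1,
                              interaction_effects = 0, noise_sd = 0.3,
                              seed = 41)
  asg <- sim$truth$module_of_probe
  eg <- module_eigengenes(sim$expr, asg)
  expect_gte(abs(stats::cor(eg$eigengenes[1, ],
                            sim$truth$latent_factors[1, ])), 0.95)
})

test_that("eigengene errors: zero-variance probe named, tiny module", {
  x <- matrix(stats::rnorm(3 * 6), 3, 6,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:6)))
  x[2, ] <- 5
  asg <- stats::setNames(rep(1L, 3), rownames(x))
  expect_error(module_eigengenes(expression_matrix(x), asg), "p2")
  one <- stats::setNames(c(1L, 0L, 0L), rownames(x))
  expect_error(module_eigengenes(toy_expr(3, 6), one), "fewer than 2")
})

test_that("eigengene is the variance-maximizing unit vector", {
  set.seed(42)
  sim <- simulate_endotoxemia(n_modules = 2, genes_per_module = 30,
                              n_background = 0, lps_effects = c(1, -1),
                              interaction_effects = c(0, 0), seed = 42)
  eg <- module_eigengenes(sim$expr, sim$truth$module_of_probe)
  x <- sim$expr$values
  for (m in 1:2) {
    idx <- sim$truth$module_of_probe == m
    z <- (x[idx, ] - rowMeans(x[idx, ])) / apply(x[idx, ], 1, stats::sd)
    ve_eig <- sum((z %*% eg$eigengenes[m, ])^2)
    for (i in 1:100) {
      v <- stats::rnorm(ncol(z)); v <- v / sqrt(sum(v^2))
      expect_lte(sum((z %*% v)^2), ve_eig + 1e-9)
    }
  }
})

test_that("kME of an eigengene-equal probe is 1; orthogonal probe is 0", {
  set.seed(43)
  sim <- simulate_endotoxemia(n_modules = 1, genes_per_module = 20,
                              n_background = 0, lps_effects = 1,
                              interaction_effects = 0, seed = 43)
  eg <- module_eigengenes(sim$expr, sim$truth$module_of_probe)
  e <- eg$eigengenes[1, ]
  u <- stats::rnorm(length(e))
  orth <- u - e * sum(u * (e - mean(e))) / sum(e * (e - mean(e)))
  # construct orthogonality in the correlation sense
  orth <- stats::residuals(stats::lm(u ~ e))
  x2 <- rbind(sim$expr$values, EQ = e, ORTH = orth)
  kme <- module_membership(expression_matrix(x2), eg)
  expect_equal(unname(kme["EQ", "ME1"]), 1, tolerance = 1e-12)
  expect_lt(abs(kme["ORTH", "ME1"]), 1e-12)
})

test_that("kME ordering matches planted loading ordering (Spearman >= 0.9)", {
  # identifiability needs a cohort large enough that correlation-estimate
  # noise does not swamp the loading spread; 50 subjects/arm with a wide
  # loading range gives that while leaving the model unchanged
  sim <- simulate_endotoxemia(n_modules = 1, genes_per_module = 50,
                              n_background = 0, subjects_per_arm = 50,
                              lps_effects = 1, interaction_effects = 0,
                              loading_range = c(0.4, 1.3), hub_loading = 2,
                              seed = 44)
  eg <- module_eigengenes(sim$expr, sim$truth$module_of_probe)
  kme <- module_membership(sim$expr, eg)
  rho <- stats::cor(kme[, "ME1"], sim$truth$loadings,
                    method = "spearman")
  expect_gte(abs(rho), 0.9)
})

test_that("kME is maximal for a probe's own planted module in >= 95% of probes", {
  set.seed(45)
  frac_own <- numeric(0)
  for (seed in 1:5) {
    sim <- simulate_endotoxemia(seed = seed)
    asg <- sim$truth$module_of_probe
    eg <- module_eigengenes(sim$expr, asg)
    kme <- module_membership(sim$expr, eg)
    planted <- asg > 0
    own <- paste0("ME", asg[planted])
    best <- colnames(kme)[max.col(abs(kme[planted, ]))]
    frac_own <- c(frac_own, mean(best == own))
  }
  expect_gte(mean(frac_own), 0.95)
})

test_that("module_significance: Bonferroni arithmetic and degenerate equality", {
  sim <- simulate_endotoxemia(seed = 46)
  fit <- wcna(sim$expr, beta = 6)
  ms <- module_significance(fit$eigengenes, sim$design, alpha = 0.05)
  M <- length(fit$eigengenes$module_ids)
  expect_equal(ms$bonferroni_alpha[1] * M, 0.05, tolerance = 1e-15)
  # identical t4 values in both arms -> t = 0, not responsive
  eg2 <- fit$eigengenes
  t4 <- sim$design$timepoint == "t4"
  v <- stats::rnorm(32)
  v[t4 & sim$design$arm == "placebo"] <- 1:8
  v[t4 & sim$design$arm == "etanercept"] <- 1:8
  eg2$eigengenes[1, ] <- v
  ms2 <- module_significance(eg2, sim$design)
  expect_equal(ms2$t_statistic[1], 0, tolerance = 1e-12)
  expect_false(ms2$responsive[1])
})

test_that("module_significance errors with < 2 post-LPS samples per arm", {
  sim <- simulate_endotoxemia(n_modules = 1, genes_per_module = 30,
                              n_background = 0, subjects_per_arm = 4,
                              lps_effects = 1, interaction_effects = 0,
                              seed = 47)
  eg <- module_eigengenes(sim$expr, sim$truth$module_of_probe)
  d <- as.data.frame(sim$design)
  d <- d[!(d$arm == "etanercept" & d$timepoint == "t4" &
             d$subject_id != "S05"), ]
  eg$sample_ids <- intersect(eg$sample_ids, d$sample_id)
  eg$eigengenes <- eg$eigengenes[, eg$sample_ids, drop = FALSE]
  expect_error(module_significance(eg, study_design(d)), "at least 2")
})

test_that("pooled t matches t.test and Welch option is exposed", {
  sim <- simulate_endotoxemia(seed = 48)
  fit <- wcna(sim$expr, beta = 6)
  ms <- module_significance(fit$eigengenes, sim$design)
  msw <- module_significance(fit$eigengenes, sim$design, welch = TRUE)
  e <- fit$eigengenes$eigengenes[1, ]
  t4 <- sim$design$timepoint == "t4"
  pl <- e[t4 & sim$design$arm == "placebo"]
  et <- e[t4 & sim$design$arm == "etanercept"]
  expect_equal(ms$t_statistic[1],
               unname(stats::t.test(pl, et, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_equal(msw$df[1],
               unname(stats::t.test(pl, et)$parameter), tolerance = 1e-12)
})

test_that("type-I error of the module test is controlled at alpha/M", {
  # null: gamma = 0 everywhere; eigengene built from planted module 1
  set.seed(49)
  M <- 10
  n_sims <- 400
  rejections <- 0
  for (i in seq_len(n_sims)) {
    sim <- simulate_endotoxemia(n_modules = 1, genes_per_module = 30,
                                n_background = 0, lps_effects = 1,
                                interaction_effects = 0,
                                seed = 100000 + i)
    eg <- module_eigengenes(sim$expr, sim$truth$module_of_probe)
    ms <- module_significance(eg, sim$design)
    if (ms$p[1] < 0.05 / M) rejections <- rejections + 1
  }
  # one-sided binomial check that the rejection rate <= alpha/M = 0.005
  bt <- stats::binom.test(rejections, n_sims, p = 0.005,
                          alternative = "greater")
  expect_gt(bt$p.value, 0.01)
})

test_that("hub selection: strict max, tie-break by |kME|, then lexicographic", {
  conn <- data.frame(probe_id = c("a", "b", "c", "d"),
                     module = c(1L, 1L, 1L, 1L),
                     kTotal = c(5, 4, 4, 3),
                     kWithin = c(3, 3, 3, 1),
                     kOut = c(2, 1, 1, 2))
  kme <- matrix(c(0.2, -0.9, 0.5, 0.1), 4, 1,
                dimnames = list(c("a", "b", "c", "d"), "ME1"))
  gs <- stats::setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  asg <- stats::setNames(rep(1L, 4), c("a", "b", "c", "d"))
  hb <- hub_genes(conn, kme, gs, asg)
  expect_identical(hb$hub_probe, "b")   # kWithin tie a/b/c -> |kME| 0.9
  conn2 <- conn; conn2$kWithin <- c(9, 1, 1, 1)
  expect_identical(hub_genes(conn2, kme, gs, asg)$hub_probe, "a")
  kme3 <- kme; kme3[, 1] <- c(0.5, 0.5, 0.5, 0.1)
  conn3 <- conn; conn3$kWithin <- c(3, 3, 3, 1)
  expect_identical(hub_genes(conn3, kme3, gs, asg)$hub_probe, "a")
})

test_that("modules smaller than 3 report an undefined GS-kME correlation", {
  conn <- data.frame(probe_id = c("a", "b"), module = c(1L, 1L),
                     kTotal = c(1, 2), kWithin = c(1, 2), kOut = c(0, 0))
  kme <- matrix(c(0.5, 0.6), 2, 1, dimnames = list(c("a", "b"), "ME1"))
  gs <- stats::setNames(c(1, 2), c("a", "b"))
  asg <- stats::setNames(c(1L, 1L), c("a", "b"))
  hb <- hub_genes(conn, kme, gs, asg)
  expect_true(is.na(hb$gs_kme_cor))
  expect_identical(hb$hub_probe, "b")
})

test_that("planted max-loading gene is selected as hub in >= 9/10 seeds", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulate_endotoxemia(seed = seed)
    fit <- wcna(sim$expr, beta = 6)
    gs <- stats::setNames(
      paired_t_fc(sim$expr, sim$design, "placebo")$statistic,
      rownames(sim$expr$values))
    hb <- hub_genes(fit$connectivity, fit$kme, gs, fit$assignment)
    if (setequal(hb$hub_probe, sim$truth$hub_probes)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("direction counts: zeros, strict boundary, hand enumeration", {
  de <- structure(data.frame(
    probe_id = paste0("p", 1:8),
    log2_fc = c(0.6, 0.5, -0.51, 0.2, 1.5, -2, 0.5, -0.5),
    statistic = 0, statistic_kind = "paired_t", df = 3,
    p = 0.5, q = 0.5),
    class = c("de_result", "data.frame"), comparison = "toy")
  asg <- stats::setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), paste0("p", 1:8))
  dc <- module_direction_counts(de, asg)
  # module 1: up only p1 (0.6 > 0.5; 0.5 not counted), down only p3
  # module 2: up p5, down p6 (0.5 and -0.5 on the boundary: neither)
  expect_identical(dc$n_up, c(1L, 1L))
  expect_identical(dc$n_down, c(1L, 1L))
  expect_true(all(dc$n_up + dc$n_down <= dc$size))
  zero <- de; zero$log2_fc <- rep(0, 8)
  dcz <- module_direction_counts(zero, asg)
  expect_identical(dcz$n_up + dcz$n_down, c(0L, 0L))
  short <- de[1:6, ]
  class(short) <- class(de)
  expect_error(module_direction_counts(short, asg), "p7")
})

test_that("eigengenes TSV writer emits module x sample rows", {
  sim <- simulate_endotoxemia(seed = 50)
  fit <- wcna(sim$expr, beta = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eigengenes(fit$eigengenes, path)
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_identical(tab$module, rownames(fit$eigengenes$eigengenes))
  expect_equal(unlist(tab[1, sample_ids(sim$expr)], use.names = FALSE),
               unname(fit$eigengenes$eigengenes[1, ]), tolerance = 1e-6)
})
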