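#' Pipeline configuration
#'
#' Collects every path and stage parameter of the end-to-end analysis.
#' `expression` and `design` may be file paths or in-memory objects
#' ([expression_matrix()] / [study_design()]).
#'
#' @param expression expression TSV path or [expression_matrix()].
#' @param design design TSV path or [study_design()].
#' @param out_dir output directory for the result bundle.
#' @param gmt optional GMT path or [gene_sets()] (enables enrichment).
#' @param probe_gene_map optional probe-to-gene TSV path or data.frame
#'   with columns `probe_id`, `gene_symbol` (required for enrichment).
#' @param scale input scale: `"raw"` triggers normalization, `"glog2"`
#'   skips it.
#' @param has_detection_p whether the expression TSV carries
#'   detection-p columns (enables the detection filter).
#' @param detection_threshold,min_detected_samples detection filter.
#' @param knn_k neighbours for [knn_impute()].
#' @param de_q_threshold q cutoff defining the network input set from
#'   the `network_arm` paired contrast (default 0.01).
#' @param network_arm arm whose LPS contrast selects network probes.
#' @param fold_threshold volcano fold-change cutoff.
#' @param beta fixed soft power; `NULL` selects by scale-free fit.
#' @param candidate_betas,rsq_target soft-threshold scan settings.
#' @param min_module_size minimum module size.
#' @param alpha familywise level for module significance.
#' @param lfc_threshold direction-count threshold.
#' @param export_threshold,export_weight_kind Cytoscape export settings.
#' @param run_enrichment,run_export stage toggles.
#' @param seed integer seed fixing any randomized stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, design, out_dir,
                            gmt = NULL, probe_gene_map = NULL,
                            scale = c("glog2", "raw"),
                            has_detection_p = FALSE,
                            detection_threshold = 0.05,
                            min_detected_samples = 1,
                            knn_k = 15,
                            de_q_threshold = 0.01,
                            network_arm = c("placebo", "etanercept"),
                            fold_threshold = 1.5,
                            beta = NULL,
                            candidate_betas = 1:20,
                            rsq_target = 0.85,
                            min_module_size = 30,
                            alpha = 0.05,
                            lfc_threshold = 0.5,
                            export_threshold = 0.1,
                            export_weight_kind = c("adjacency", "tom"),
                            run_enrichment = TRUE,
                            run_export = TRUE,
                            seed = 1) {
  scale <- match.arg(scale)
  network_arm <- match.arg(network_arm)
  export_weight_kind <- match.arg(export_weight_kind)
  if (detection_threshold <= 0 || detection_threshold >= 1)
    stop("'detection_threshold' must lie in (0, 1)")
  if (de_q_threshold <= 0 || de_q_threshold > 1)
    stop("'de_q_threshold' must lie in (0, 1]")
  if (export_threshold < 0 || export_threshold >= 1)
    stop("'export_threshold' must lie in [0, 1)")
  if (knn_k < 1) stop("'knn_k' must be at least 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in setdiff(names(x), c("expression", "design", "gmt",
                                 "probe_gene_map")))
    cat(sprintf("  %s = %s\n", nm,
                paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  attr(res, "elapsed") <- proc.time()[["elapsed"]] - t0
  res
}

fmt_param <- function(v) {
  if (is.null(v)) "NULL" else paste(format(v, digits = 15), collapse = ",")
}

#' Run the full co-expression analysis pipeline
#'
#' Executes filter, impute, normalize, paired differential expression
#' per arm, nested-model ANOVA, network construction on the probes
#' passing the configured DE q threshold, module detection, module
#' statistics, optional enrichment, and optional Cytoscape export.
#' All stage tables, a parameter manifest with input checksums
#' (`manifest.txt`) and a plain-text run log (`run_log.txt`) are
#' written into `config$out_dir`.
#'
#' Identical config and inputs give byte-identical stage tables and
#' manifest; the run log additionally carries wall-clock stage timings
#' and is the one file excluded from that guarantee. A stage error
#' aborts the run with the stage name and cause, and leaves a `FAILED`
#' marker file naming the stage in the output directory.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results (`expr`, `de`,
#'   `anova`, `fit`, `module_stats`, `enrichment`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log_lines <- character(0)
  timings <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  set.seed(as.integer(config$seed))

  run <- function() {
    # --- input stage -----------------------------------------------------
    checks <- character(0)
    expr <- pipeline_stage("read_expression",
      if (inherits(config$expression, "expression_matrix"))
        config$expression
      else read_expression_matrix(config$expression,
                                  has_detection_p = config$has_detection_p,
                                  scale = config$scale))
    design <- pipeline_stage("read_design",
      if (inherits(config$design, "study_design")) config$design
      else read_study_design(config$design))
    if (is.character(config$expression))
      checks <- c(checks, sprintf("expression md5 %s",
                                  unname(tools::md5sum(config$expression))))
    if (is.character(config$design))
      checks <- c(checks, sprintf("design md5 %s",
                                  unname(tools::md5sum(config$design))))
    note("input: %d probes x %d samples", nrow(expr$values),
         ncol(expr$values))

    # --- preprocess ------------------------------------------------------
    if (!is.null(expr$detection_p)) {
      expr <- pipeline_stage("filter_detected",
        filter_detected(expr, config$detection_threshold,
                        config$min_detected_samples))
      note("detection filter (p < %g, >= %d sample(s)): %d probes kept",
           config$detection_threshold, config$min_detected_samples,
           nrow(expr$values))
    }
    if (any(is.na(expr$values))) {
      n_miss <- sum(is.na(expr$values))
      expr <- pipeline_stage("knn_impute",
                             knn_impute(expr, k = config$knn_k))
      note("knn imputation (k = %d): %d cells imputed", config$knn_k,
           n_miss)
    }
    if (expr$scale == "raw") {
      nz <- pipeline_stage("vsn_normalize", vsn_normalize(expr))
      expr <- nz$expr
      write_normalization_fit(nz$fit, file.path(out, "normalization.tsv"))
      note("normalization: glog2 scale, c = %.6g", nz$fit$c)
    }
    write_expression_matrix(expr, file.path(out, "expression_normalized.tsv"))

    # --- differential expression ----------------------------------------
    de <- list()
    for (arm in c("placebo", "etanercept")) {
      de[[arm]] <- pipeline_stage(paste0("paired_de_", arm),
                                  paired_t_fc(expr, design, arm))
      write_de_result(de[[arm]], file.path(out, paste0("de_", arm, ".tsv")))
      vc <- volcano_classify(de[[arm]], config$de_q_threshold,
                             config$fold_threshold)
      note("paired DE (%s): %d probes with q < %g; %d volcano-flagged",
           arm, sum(de[[arm]]$q < config$de_q_threshold),
           config$de_q_threshold, vc$n_flagged)
    }
    an <- pipeline_stage("nested_anova",
                         nested_model_ftest(expr, design))
    write_de_result(an, file.path(out, "anova.tsv"))
    note("nested ANOVA: %d probes with q < 0.05", sum(an$q < 0.05))

    # --- network and modules --------------------------------------------
    net_probes <- de[[config$network_arm]]$probe_id[
      de[[config$network_arm]]$q < config$de_q_threshold]
    note("network input: %d probes (%s arm, q < %g)",
         length(net_probes), config$network_arm, config$de_q_threshold)
    pipeline_stage("network_input", {
      if (length(net_probes) < config$min_module_size)
        stop("only ", length(net_probes), " probe(s) pass the q < ",
             config$de_q_threshold, " gate; need at least ",
             config$min_module_size)
      length(net_probes)
    })
    sub <- expression_matrix(
      expr$values[net_probes, , drop = FALSE],
      detection_p = if (is.null(expr$detection_p)) NULL
                    else expr$detection_p[net_probes, , drop = FALSE],
      scale = expr$scale)
    fit <- pipeline_stage("wcna",
      wcna(sub, beta = config$beta,
           params = network_params(min_module_size = config$min_module_size,
                                   rsq_target = config$rsq_target)))
    note("network: beta = %g; %d module(s); %d unassigned probes",
         fit$beta, fit$n_modules, sum(fit$assignment == 0))
    utils::write.table(
      data.frame(probe_id = names(fit$assignment),
                 module = as.integer(fit$assignment)),
      file.path(out, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (fit$n_modules == 0)
      stop("no modules detected; nothing to summarize")
    write_eigengenes(fit$eigengenes, file.path(out, "eigengenes.tsv"))
    utils::write.table(
      data.frame(probe_id = rownames(fit$kme), fit$kme,
                 check.names = FALSE),
      file.path(out, "kme.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(fit$connectivity,
                       file.path(out, "connectivity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    # --- module statistics ----------------------------------------------
    gs <- stats::setNames(de$placebo$statistic, de$placebo$probe_id)
    signif <- pipeline_stage("module_significance",
      module_significance(fit$eigengenes, design, alpha = config$alpha))
    hubs <- pipeline_stage("hub_genes",
      hub_genes(fit$connectivity, fit$kme, gs, fit$assignment))
    dirs <- pipeline_stage("module_direction_counts",
      module_direction_counts(de[[config$network_arm]], fit$assignment,
                              config$lfc_threshold))
    stats_tbl <- module_stats_table(fit$connectivity, hubs, signif, dirs)
    utils::write.table(stats_tbl, file.path(out, "module_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("module stats: %d responsive of %d at bonferroni alpha %.4g",
         sum(stats_tbl$responsive), nrow(stats_tbl),
         stats_tbl$bonferroni_alpha[1])

    # --- enrichment ------------------------------------------------------
    enr <- NULL
    if (config$run_enrichment && !is.null(config$gmt) &&
        !is.null(config$probe_gene_map)) {
      sets <- if (inherits(config$gmt, "gene_sets")) config$gmt
              else read_gmt(config$gmt)
      pg <- if (is.data.frame(config$probe_gene_map)) config$probe_gene_map
            else read_probe_gene_map(config$probe_gene_map)
      universe <- probes_to_genes(rownames(expr$values), pg)
      enr <- list()
      for (m in sort(unique(fit$assignment[fit$assignment > 0]))) {
        genes <- probes_to_genes(
          names(fit$assignment)[fit$assignment == m], pg)
        enr[[as.character(m)]] <- pipeline_stage(
          paste0("enrichment_module_", m),
          ora_hypergeometric(genes, universe, sets))
      }
      enr_tbl <- do.call(rbind, lapply(names(enr), function(m)
        cbind(module = as.integer(m), enr[[m]])))
      utils::write.table(enr_tbl, file.path(out, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("enrichment: %d module(s) x %d set(s)", length(enr),
           length(sets$sets))
    }

    # --- export ----------------------------------------------------------
    if (config$run_export) {
      pipeline_stage("export_cytoscape",
        export_cytoscape(fit$network, fit$assignment, out,
                         weight_threshold = config$export_threshold,
                         weight_kind = config$export_weight_kind,
                         hub_probes = hubs$hub_probe))
      note("export: edges.tsv / nodes.tsv / network.sif (weight > %g, %s)",
           config$export_threshold, config$export_weight_kind)
    }

    # --- manifest and log -------------------------------------------------
    # out_dir is omitted so that runs of one config into two directories
    # produce byte-identical manifests
    params <- config[!vapply(config, function(v)
      inherits(v, c("expression_matrix", "study_design", "gene_sets")) ||
        is.data.frame(v), TRUE)]
    params$out_dir <- NULL
    manifest <- c("coexmod pipeline manifest",
                  sprintf("%s = %s", names(params),
                          vapply(params, fmt_param, "")),
                  checks)
    writeLines(manifest, file.path(out, "manifest.txt"))
    list(expr = expr, de = de, anova = an, fit = fit,
         module_stats = stats_tbl, enrichment = enr, out_dir = out)
  }

  result <- tryCatch(run(), error = function(e) {
    writeLines(conditionMessage(e), failed_marker)
    stop(e)
  })
  writeLines(c(log_lines,
               sprintf("total elapsed %.2f s",
                       proc.time()[["elapsed"]])),
             file.path(out, "run_log.txt"))
  invisible(result)
}
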