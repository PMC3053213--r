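# End-to-end workflow: configuration handling and the wired
# preprocess -> scan -> select -> replicate -> sensitivity -> enrich run.

#' Default pipeline configuration
#'
#' Returns the nested configuration list the pipeline consumes.  Any element
#' can be overridden by the `...` arguments (top-level keys replace whole
#' sub-lists when given).  The configuration round-trips through JSON via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param ... top-level overrides (`paths`, `simulate`, `model`,
#'   `bootstrap`, `preprocess`, `alpha`, `fdr_method`, `sensitivity`,
#'   `enrichment`).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    paths = list(matrix = NULL, manifest = NULL,
                 rep_matrix = NULL, rep_manifest = NULL,
                 annotation_gene = NULL, annotation_term = NULL,
                 output_dir = "tvide_run"),
    simulate = list(enabled = FALSE,
                    template = "cardiogene", rep_template = "decode",
                    n_subjects = NULL, rep_n_subjects = NULL,
                    seed = 1L,
                    signal = list()),
    model = list(degree = 1L, knot_policy = "median_followup", knot = NULL),
    bootstrap = list(n = 1000L, scheme = "subject_block_residual",
                     seed = 1L),
    alpha = 0.05,
    fdr_method = "bh",
    preprocess = list(floor_threshold = 6.0, floor_fraction = 2 / 3,
                      covariate_adjust = TRUE, sex_markers = NULL,
                      drop_sex_mismatch = FALSE),
    sensitivity = list(enabled = FALSE, set_size = 46L, n_iterations = 100L,
                       exclude_selected = TRUE),
    enrichment = list(enabled = FALSE, mode = "fisher")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stopf("validation error: alpha must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file path.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("validation error: config not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as JSON
#' @param config `pipeline_config` list.
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

load_or_simulate_cohort <- function(cfg, which = c("discovery", "replication")) {
  which <- match.arg(which)
  p <- cfg$paths
  mk <- if (which == "discovery") p$matrix else p$rep_matrix
  mf <- if (which == "discovery") p$manifest else p$rep_manifest
  if (!is.null(mk) && !is.null(mf)) {
    for (f in c(mk, mf)) {
      if (!file.exists(f)) stopf("validation error: input not found: %s", f)
    }
    return(list(matrix = read_expression_matrix(mk),
                manifest = read_sample_manifest(mf),
                truth = NULL))
  }
  if (!isTRUE(cfg$simulate$enabled)) {
    stopf("validation error: %s matrix/manifest paths missing and simulation disabled",
          which)
  }
  sim <- cfg$simulate
  template <- if (which == "discovery") sim$template else sim$rep_template
  n_subj <- if (which == "discovery") sim$n_subjects else sim$rep_n_subjects
  design_args <- list(template = template)
  if (!is.null(n_subj)) design_args$n_subjects <- n_subj
  design <- do.call(cohort_design, design_args)
  seed <- as.integer(sim$seed %||% 1L) + if (which == "discovery") 0L else 1000L
  manifest <- simulate_manifest(design, seed = seed)
  spec <- do.call(signal_spec, sim$signal %||% list())
  expr <- simulate_expression(manifest, spec, seed = seed + 1L)
  list(matrix = expr$matrix, manifest = manifest, truth = expr$truth)
}

#' Run the full discovery-to-enrichment pipeline
#'
#' Executes, in order: input loading (or cohort simulation), probe QC
#' filtering, age/sex adjustment, the genome-wide time-course scan, FDR
#' selection, replication of the selected set in the second cohort, the
#' random-set sensitivity analysis (optional) and category
#' over-representation (optional).  All result tables, the configuration
#' echo and every consumed seed are written under `output_dir`; re-running
#' with the same configuration reproduces the tables byte-for-byte.
#'
#' @param config a `pipeline_config` list or a path to a JSON config.
#' @param output_dir overrides `config$paths$output_dir` when given.
#' @return (invisibly) list with `results`, `selected`, `replication`,
#'   `sensitivity`, `enrichment`, `filter_report`, `output_dir`.
#' @export
run_full_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  out_dir <- output_dir %||% cfg$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("tvide pipeline run"),
                 sprintf("bootstrap.n=%d scheme=%s seed=%d",
                         cfg$bootstrap$n, cfg$bootstrap$scheme,
                         cfg$bootstrap$seed),
                 sprintf("alpha=%g fdr=%s degree=%d knot_policy=%s",
                         cfg$alpha, cfg$fdr_method, cfg$model$degree,
                         cfg$model$knot_policy))
  write_pipeline_config(cfg, file.path(out_dir, "config.json"))

  disc <- load_or_simulate_cohort(cfg, "discovery")
  repl <- load_or_simulate_cohort(cfg, "replication")
  if (!is.null(disc$truth)) {
    ground_truth_table(disc$truth, file.path(out_dir, "ground_truth.tsv"))
  }

  # preprocess
  filt <- filter_low_expression(disc$matrix,
                                threshold = cfg$preprocess$floor_threshold,
                                fraction = cfg$preprocess$floor_fraction)
  mat <- filt$matrix
  log_lines <- c(log_lines,
                 sprintf("qc filter: removed %d of %d probes",
                         filt$report$n_removed, filt$report$n_input_probes))
  utils::write.table(
    data.frame(probe_id = filt$report$removed_probe_ids),
    file.path(out_dir, "filter_removed.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(cfg$preprocess$covariate_adjust)) {
    mat <- adjust_age_sex(mat, disc$manifest)
  }
  rep_mat <- filter_low_expression(repl$matrix,
                                   threshold = cfg$preprocess$floor_threshold,
                                   fraction = cfg$preprocess$floor_fraction)$matrix
  if (isTRUE(cfg$preprocess$covariate_adjust)) {
    rep_mat <- adjust_age_sex(rep_mat, repl$manifest)
  }
  if (!is.null(cfg$preprocess$sex_markers)) {
    sc <- sex_check(mat, disc$manifest,
                    intersect(cfg$preprocess$sex_markers, rownames(mat)))
    utils::write.table(sc, file.path(out_dir, "sex_check.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(cfg$preprocess$drop_sex_mismatch)) {
      bad <- sc$sample_id[which(sc$mismatch_flag)]
      mat <- mat[, !colnames(mat) %in% bad, drop = FALSE]
      log_lines <- c(log_lines,
                     sprintf("dropped %d sex-mismatched sample(s)", length(bad)))
    }
  }

  ann <- if (!is.null(cfg$paths$annotation_gene)) {
    read_annotation(cfg$paths$annotation_gene, cfg$paths$annotation_term)
  } else NULL

  # scan + select
  results <- run_timecourse_scan(mat, disc$manifest,
                                 n_bootstrap = cfg$bootstrap$n,
                                 seed = cfg$bootstrap$seed,
                                 degree = cfg$model$degree,
                                 knot_policy = cfg$model$knot_policy,
                                 knot = cfg$model$knot,
                                 scheme = cfg$bootstrap$scheme,
                                 fdr_method = cfg$fdr_method,
                                 alpha = cfg$alpha,
                                 annotation = ann)
  write_results_table(results, file.path(out_dir, "results.tsv"))
  selected <- select_significant(results, cfg$alpha)
  writeLines(selected, file.path(out_dir, "selected_probes.txt"))
  log_lines <- c(log_lines,
                 sprintf("scan: %d probes tested, %d selected at q<%g (seed %d)",
                         nrow(results), length(selected), cfg$alpha,
                         cfg$bootstrap$seed))

  # replication
  replication <- replicate_selected(selected, rep_mat, repl$manifest,
                                    n_bootstrap = cfg$bootstrap$n,
                                    seed = cfg$bootstrap$seed,
                                    degree = cfg$model$degree,
                                    knot_policy = cfg$model$knot_policy,
                                    knot = cfg$model$knot,
                                    scheme = cfg$bootstrap$scheme,
                                    fdr_method = cfg$fdr_method,
                                    alpha = cfg$alpha)
  utils::write.table(replication$results,
                     file.path(out_dir, "replication.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("replication: %d of %d probes replicated",
                         replication$n_replicated, length(selected)))

  # sensitivity
  sensitivity <- NULL
  if (isTRUE(cfg$sensitivity$enabled)) {
    excl <- if (isTRUE(cfg$sensitivity$exclude_selected)) selected else character()
    sensitivity <- sensitivity_null_sets(
      rownames(rep_mat), rep_mat, repl$manifest,
      set_size = cfg$sensitivity$set_size,
      n_iterations = cfg$sensitivity$n_iterations,
      seed = cfg$bootstrap$seed, exclude = excl,
      n_bootstrap = cfg$bootstrap$n, alpha = cfg$alpha,
      degree = cfg$model$degree, knot_policy = cfg$model$knot_policy,
      scheme = cfg$bootstrap$scheme, fdr_method = cfg$fdr_method)
    suppressMessages(write_sensitivity_summary(
      sensitivity, file.path(out_dir, "sensitivity.tsv")))
    log_lines <- c(log_lines,
                   sprintf("sensitivity: median %g mean %.3g max %d",
                           sensitivity$median, sensitivity$mean,
                           sensitivity$max))
  }

  # enrichment
  enrichment <- NULL
  if (isTRUE(cfg$enrichment$enabled) && !is.null(ann) &&
      nrow(ann$probe_to_terms)) {
    uni_genes <- unique(stats::na.omit(
      map_probes_to_genes(rownames(mat), ann)$mapping$gene_symbol))
    sel_genes <- unique(stats::na.omit(
      map_probes_to_genes(selected, ann)$mapping$gene_symbol))
    enrichment <- fisher_overrepresentation(sel_genes, uni_genes, ann,
                                            mode = cfg$enrichment$mode,
                                            alpha = cfg$alpha)
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(results = results, selected = selected,
                 replication = replication, sensitivity = sensitivity,
                 enrichment = enrichment, filter_report = filt$report,
                 output_dir = out_dir))
}
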