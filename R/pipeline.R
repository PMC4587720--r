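#' Run the full methylation-landscape analysis in memory
#'
#' Executes the stages in dependency order: per-CpG summaries and the
#' variability threshold on the normal cohort, HVM flagging,
#' methylation-expression correlation (when expression is supplied), tumor
#' differential calls plus demethylation-response integration (when tumor
#' samples and treatment expression are supplied), and the landscape
#' classification. Stages whose inputs are absent are skipped with an
#' explicit notice in the run summary.
#'
#' @param beta A \code{beta_matrix} whose sample groups mark the normal
#'   cohort, the normal reference, and tumor lines.
#' @param map A \code{probe_gene_map}.
#' @param panel A \code{gene_panel}.
#' @param config An \code{analysis_config}.
#' @param expr Optional raw \code{expression_matrix} for the matched normals.
#' @param expr_dac_control,expr_dac_treated Optional cell-line expression
#'   (control matrix; treated = named list of condition matrices).
#' @param normal_group,reference_group,tumor_group Sample-group labels.
#' @return List of class \code{methscape_run}: variability (threshold,
#'   table), correlation (table or NULL), tumor (hyper_status, dac, regulated
#'   or NULL), classification (table, counts), summary (RunSummary list).
#' @export
run_pipeline <- function(beta, map, panel, config = analysis_config(),
                         expr = NULL, expr_dac_control = NULL,
                         expr_dac_treated = NULL,
                         normal_group = "adult_liver",
                         reference_group = "reference_normal",
                         tumor_group = "hepatoma_line") {
  notices <- character(0)
  normals <- samples_in_group(beta, normal_group)
  if (length(normals) < 2) stop("need >= 2 normal-cohort samples")

  ## stage 1: variability ---------------------------------------------------
  summaries <- suppressWarnings(cpg_summaries(beta, normals))
  panel_genes <- panel$panel_genes$gene
  ctrl_var <- gene_variability_table(summaries, map,
                                     panel$control_methylation_genes,
                                     config$region_set_5prime)
  threshold <- derive_variability_threshold(ctrl_var)
  panel_var <- gene_variability_table(summaries, map, panel_genes,
                                      config$region_set_5prime)
  hvm <- flag_hvm_genes(panel_var, threshold)

  ## stage 2: correlation + expression CV -----------------------------------
  correlation <- NULL; cv_table <- NULL; theta_cv <- NA_real_
  inverse_genes <- character(0)
  if (!is.null(expr)) {
    nexpr <- if (expr$normalization_state == "raw")
      normalize_percentile75(expr) else expr
    matched <- intersect(colnames(beta$values)[colnames(beta$values) %in% normals],
                         colnames(nexpr$values))
    if (length(matched) < config$min_pairs_for_correlation)
      stop("fewer matched beta/expression samples than min_pairs_for_correlation")
    ctrl_cv <- do.call(rbind, lapply(panel$control_expression_genes,
                                     function(g) expression_cv(nexpr, g, matched)))
    theta_cv <- derive_cv_threshold(ctrl_cv)
    cv_table <- do.call(rbind, lapply(panel_genes, function(g)
      expression_cv(nexpr, g, matched)))
    correlation <- do.call(rbind, lapply(panel_genes, function(g)
      correlate_gene(g, beta, nexpr, map, config, summaries,
                     threshold$value, matched)))
    rownames(correlation) <- NULL
    inverse_genes <- unique(correlation$gene[correlation$inverse_significant])
  } else {
    notices <- c(notices, "expression input absent: correlation and HKG expression criteria skipped")
  }

  ## stage 3: tumor ---------------------------------------------------------
  tumor <- NULL
  lines <- samples_in_group(beta, tumor_group)
  refs <- samples_in_group(beta, reference_group)
  if (length(lines) && length(refs)) {
    calls <- do.call(rbind, lapply(lines, function(cl)
      differential_calls(beta, cl, refs[1], config)))
    hyper_status <- do.call(rbind, lapply(panel_genes, function(g)
      gene_hypermethylation(calls, map, g, config$region_set_5prime)))
    dac <- NULL; regulated <- NULL
    if (!is.null(expr_dac_control) && !is.null(expr_dac_treated)) {
      dac <- do.call(rbind, lapply(panel_genes, function(g)
        do.call(rbind, lapply(lines, function(cl)
          dac_response(expr_dac_control, expr_dac_treated, g, cl, config)))))
      regulated <- integrate_regulated_genes(hyper_status, dac, panel)
    } else {
      notices <- c(notices, "treatment expression absent: demethylation response and integration skipped")
    }
    tumor <- list(calls = calls, hyper_status = hyper_status, dac = dac,
                  regulated = regulated)
  } else {
    notices <- c(notices, "no tumor lines or reference in beta matrix: tumor stage skipped")
  }

  ## stage 4: classification ------------------------------------------------
  bundles <- lapply(panel_genes, function(g) {
    evidence_bundle(
      gene = g,
      variability = panel_var[panel_var$gene == g, , drop = FALSE],
      inverse_correlated = if (is.null(correlation)) NA else g %in% inverse_genes,
      hyper_status = if (!is.null(tumor))
        tumor$hyper_status[tumor$hyper_status$gene == g, , drop = FALSE] else NULL,
      dac_responses = if (!is.null(tumor) && !is.null(tumor$dac))
        tumor$dac[tumor$dac$gene == g, , drop = FALSE] else NULL,
      expression_cv = if (!is.null(cv_table))
        cv_table[cv_table$gene == g, , drop = FALSE] else NULL,
      summaries = summaries, map = map, config = config)
  })
  classification <- classify_panel(bundles, threshold$value, theta_cv, config)

  summary <- list(
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("methscape")),
    n_panel_genes = length(panel_genes),
    n_normal_samples = length(normals),
    n_tumor_lines = length(lines),
    variability_threshold = threshold$value,
    cv_threshold_percent = theta_cv,
    n_hvm_flagged = hvm$n_flagged,
    n_scored = hvm$n_scored,
    n_inverse_correlated = length(inverse_genes),
    n_hyper_genes = if (!is.null(tumor))
      length(unique(tumor$hyper_status$gene[tumor$hyper_status$hypermethylated]))
      else NA_integer_,
    n_dac_responsive = if (!is.null(tumor) && !is.null(tumor$dac))
      length(unique(tumor$dac$gene[tumor$dac$responsive %in% TRUE]))
      else NA_integer_,
    n_regulated = if (!is.null(tumor) && !is.null(tumor$regulated))
      nrow(tumor$regulated) else NA_integer_,
    class_counts = classification$counts,
    notices = notices
  )
  structure(list(variability = list(threshold = threshold, table = hvm$table,
                                    controls = ctrl_var),
                 correlation = correlation, expression_cv = cv_table,
                 tumor = tumor, classification = classification,
                 summary = summary),
            class = "methscape_run")
}

#' @export
print.methscape_run <- function(x, ...) {
  s <- x$summary
  cat("methscape run\n")
  cat(sprintf("  variability threshold: %.4f; HVM flagged: %d / %d scored\n",
              s$variability_threshold, s$n_hvm_flagged, s$n_scored))
  if (!is.na(s$cv_threshold_percent))
    cat(sprintf("  CV threshold: %.2f%%; inverse-correlated genes: %d\n",
                s$cv_threshold_percent, s$n_inverse_correlated))
  if (!is.na(s$n_regulated))
    cat(sprintf("  methylation-regulated genes: %d\n", s$n_regulated))
  cat("  classes:", paste(sprintf("%s=%d", names(s$class_counts),
                                  s$class_counts), collapse = ", "), "\n")
  for (n in s$notices) cat("  note:", n, "\n")
  invisible(x)
}

#' Run the pipeline from a config file and write stage outputs
#'
#' The YAML/JSON config references the input files (beta, manifest, panel,
#' sample groups, optional expression and treatment matrices) and an output
#' directory. Stage tables are written as TSV and the run summary as JSON;
#' identical inputs and config yield byte-identical outputs.
#'
#' @param config_path Path to the run config (fields: beta, manifest, panel,
#'   sample_groups, outdir; optional expression, dac_control, dac_treated
#'   (named map condition -> path), and an \code{analysis} block of
#'   \code{\link{analysis_config}} overrides).
#' @return The \code{methscape_run} object, invisibly.
#' @export
methscape_run <- function(config_path) {
  raw <- if (grepl("\\.json$", config_path, ignore.case = TRUE))
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  else yaml::read_yaml(config_path)
  for (f in c("beta", "manifest", "panel", "sample_groups", "outdir"))
    if (is.null(raw[[f]])) stop("run config lacks field '", f, "'")
  cfg <- do.call(analysis_config, if (is.null(raw$analysis)) list() else raw$analysis)
  grp <- utils::read.table(raw$sample_groups, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  sg <- stats::setNames(grp$group, grp$sample_id)
  beta <- read_beta_matrix(raw$beta, sg)
  panel <- read_gene_panel(raw$panel)
  map <- build_probe_gene_map(read_manifest(raw$manifest), panel)
  expr <- if (!is.null(raw$expression)) read_expression_matrix(raw$expression) else NULL
  dc <- if (!is.null(raw$dac_control)) read_expression_matrix(raw$dac_control) else NULL
  dt <- if (!is.null(raw$dac_treated))
    lapply(raw$dac_treated, read_expression_matrix) else NULL
  res <- run_pipeline(beta, map, panel, cfg, expr, dc, dt)
  outdir <- raw$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_table(res$variability$table, file.path(outdir, "variability.tsv"))
  if (!is.null(res$correlation))
    write_table(res$correlation, file.path(outdir, "correlation.tsv"))
  if (!is.null(res$tumor)) {
    write_table(res$tumor$hyper_status, file.path(outdir, "tumor_hyper.tsv"))
    if (!is.null(res$tumor$dac))
      write_table(res$tumor$dac, file.path(outdir, "dac_response.tsv"))
    if (!is.null(res$tumor$regulated))
      write_table(res$tumor$regulated, file.path(outdir, "regulated_genes.tsv"))
  }
  write_table(res$classification$table, file.path(outdir, "classes.tsv"))
  s <- res$summary
  s$class_counts <- as.list(s$class_counts)
  jsonlite::write_json(s, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Export a matrix reordered by average-linkage hierarchical clustering
#'
#' Rows and columns are reordered by average-linkage clustering on Euclidean
#' distance (the ordering a heat-map renderer would use); the ordered values
#' are exported, rendering is left to external tools. Probes with missing
#' values are dropped before clustering.
#'
#' @param beta A \code{beta_matrix} (or plain matrix) submatrix.
#' @param path Optional TSV output path.
#' @return The reordered matrix, invisibly if \code{path} is given.
#' @export
export_clustered_matrix <- function(beta, path = NULL) {
  m <- if (inherits(beta, "beta_matrix")) beta$values else as.matrix(beta)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need >= 2 complete probes and >= 2 samples to cluster")
  leaf_order <- function(x, w) {
    d <- stats::as.dendrogram(stats::hclust(stats::dist(x), method = "average"))
    # orient branches by mean weight so the ordering does not depend on the
    # input row order
    stats::order.dendrogram(stats::reorder(d, w, agglo.FUN = mean))
  }
  ro <- leaf_order(m, rowMeans(m))
  co <- leaf_order(t(m), colMeans(m))
  out <- m[ro, co, drop = FALSE]
  if (!is.null(path)) {
    write_matrix(out, path, id_column = "probe_id")
    return(invisible(out))
  }
  out
}
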