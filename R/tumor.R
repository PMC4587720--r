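#' Differential methylation calls: tumor line versus normal reference
#'
#' For every probe with beta values in both samples, computes
#' delta_beta = beta_cell - beta_ref and calls direction hyper when
#' delta_beta exceeds the cutoff, hypo when it falls below the negated
#' cutoff (strict inequalities), else none. An alternative absolute-level
#' mode (\code{tumor_call_mode = "absolute"} in the config) calls hyper when
#' beta_cell > cutoff and beta_ref <= cutoff, mirrored for hypo.
#'
#' @param beta A \code{beta_matrix} containing both samples.
#' @param cell_line_sample Sample ID of the tumor line.
#' @param reference_sample Sample ID of the normal reference.
#' @param config An \code{analysis_config}.
#' @return data.frame: probe_id, cell_line, beta_cell, beta_ref, delta_beta,
#'   direction.
#' @export
differential_calls <- function(beta, cell_line_sample, reference_sample,
                               config = analysis_config()) {
  m <- beta$values
  for (s in c(cell_line_sample, reference_sample))
    if (!s %in% colnames(m)) stop("sample '", s, "' not in beta matrix")
  bc <- m[, cell_line_sample]
  br <- m[, reference_sample]
  keep <- !is.na(bc) & !is.na(br)
  bc <- bc[keep]; br <- br[keep]
  delta <- bc - br
  cut <- config$delta_beta_cutoff
  direction <- if (config$tumor_call_mode == "absolute") {
    ifelse(bc > cut & br <= cut, "hyper",
           ifelse(bc <= cut & br > cut, "hypo", "none"))
  } else {
    ifelse(delta > cut, "hyper", ifelse(delta < -cut, "hypo", "none"))
  }
  data.frame(probe_id = rownames(m)[keep], cell_line = cell_line_sample,
             beta_cell = unname(bc), beta_ref = unname(br),
             delta_beta = unname(delta), direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-level 5'-regulatory hypermethylation status per cell line
#'
#' TRUE iff at least one 5' regulatory probe of the gene carries a hyper
#' call in that line; body-only hypermethylation does not qualify.
#'
#' @param calls Output of \code{\link{differential_calls}} (one line, or
#'   several lines row-bound).
#' @param map A \code{probe_gene_map}.
#' @param gene Gene symbol.
#' @param region_set 5' regulatory region groups.
#' @return data.frame: gene, cell_line, hypermethylated, n_hyper_probes,
#'   hyper_probes (semicolon-joined).
#' @export
gene_hypermethylation <- function(calls, map, gene,
                                  region_set = c("TSS1500", "TSS200", "FIVE_UTR")) {
  probes <- gene_probes(map, gene, region_set)$probe_id
  out <- lapply(unique(calls$cell_line), function(cl) {
    sub <- calls[calls$cell_line == cl & calls$probe_id %in% probes &
                   calls$direction == "hyper", , drop = FALSE]
    data.frame(gene = gene, cell_line = cl,
               hypermethylated = nrow(sub) > 0, n_hyper_probes = nrow(sub),
               hyper_probes = paste(sub$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Demethylating-treatment expression response of one gene in one line
#'
#' Fold change is the maximum treated/control ratio over the supplied
#' treated conditions (several DAC doses or DAC+TSA combinations are
#' condition columns); responsive iff fold change strictly exceeds the
#' cutoff. Conditions whose names indicate TSA alone (no DAC) are excluded
#' unless \code{config$include_tsa} is set, since histone-deacetylase
#' inhibition alone is not a demethylation response.
#'
#' @param expr_control An \code{expression_matrix} of untreated values with
#'   one column per cell line.
#' @param expr_treated A named list of \code{expression_matrix} objects, one
#'   per treated condition, same cell-line columns.
#' @param gene Gene symbol.
#' @param cell_line Cell-line column name.
#' @param config An \code{analysis_config}.
#' @return One-row data.frame: gene, cell_line, fold_change, responsive,
#'   best_condition, defined.
#' @export
dac_response <- function(expr_control, expr_treated, gene, cell_line,
                         config = analysis_config()) {
  if (!is.list(expr_treated) || inherits(expr_treated, "expression_matrix"))
    expr_treated <- list(treated = expr_treated)
  if (!config$include_tsa) {
    nm <- names(expr_treated)
    tsa_only <- grepl("tsa", nm, ignore.case = TRUE) &
      !grepl("dac", nm, ignore.case = TRUE)
    expr_treated <- expr_treated[!tsa_only]
  }
  if (length(expr_treated) == 0) stop("no treated conditions to score")
  ctrl <- gene_expression_values(expr_control, gene, cell_line)
  if (is.null(ctrl) || is.na(ctrl))
    stop("no control expression for gene ", gene, " in line ", cell_line)
  if (ctrl == 0) {
    return(data.frame(gene = gene, cell_line = cell_line,
                      fold_change = NA_real_, responsive = NA,
                      best_condition = NA_character_, defined = FALSE,
                      stringsAsFactors = FALSE))
  }
  folds <- vapply(expr_treated, function(em) {
    tv <- gene_expression_values(em, gene, cell_line)
    if (is.null(tv) || is.na(tv)) NA_real_ else tv / ctrl
  }, numeric(1))
  if (all(is.na(folds))) stop("no treated expression for gene ", gene)
  i <- which.max(folds)
  data.frame(gene = gene, cell_line = cell_line, fold_change = folds[[i]],
             responsive = folds[[i]] > config$fold_change_cutoff,
             best_condition = names(folds)[i], defined = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integrate hypermethylation and demethylation response into regulated calls
#'
#' A gene is called "regulated by DNA methylation" iff some single cell line
#' shows both a 5'-regulatory hyper call and a demethylation expression
#' response; evidence from different lines is never combined.
#'
#' @param hyper_status data.frame of \code{\link{gene_hypermethylation}} rows
#'   over all genes and lines.
#' @param dac_responses data.frame of \code{\link{dac_response}} rows over
#'   the same genes and lines.
#' @param panel Optional \code{gene_panel}; restricts calls to panel genes.
#' @return data.frame: gene, supporting_lines (semicolon-joined), n_lines.
#' @export
integrate_regulated_genes <- function(hyper_status, dac_responses, panel = NULL) {
  merged <- merge(hyper_status[, c("gene", "cell_line", "hypermethylated")],
                  dac_responses[, c("gene", "cell_line", "responsive")],
                  by = c("gene", "cell_line"))
  merged$support <- merged$hypermethylated & merged$responsive %in% TRUE
  if (!is.null(panel))
    merged <- merged[merged$gene %in% panel$panel_genes$gene, , drop = FALSE]
  sup <- merged[merged$support, , drop = FALSE]
  if (nrow(sup) == 0) {
    return(data.frame(gene = character(0), supporting_lines = character(0),
                      n_lines = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(sup, sup$gene), function(d) {
    data.frame(gene = d$gene[1],
               supporting_lines = paste(sort(unique(d$cell_line)), collapse = ";"),
               n_lines = length(unique(d$cell_line)), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
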