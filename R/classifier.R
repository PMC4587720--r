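#' Assemble a per-gene evidence bundle
#'
#' Collects the inputs the landscape classifier needs for one gene:
#' inter-individual variability, inverse methylation-expression correlation,
#' tumor hypermethylation and demethylation-response lines, expression CV,
#' and the median beta of each 5' regulatory and gene-body probe.
#'
#' @param gene Gene symbol.
#' @param variability One-row gene variability result (or NULL).
#' @param inverse_correlated Logical (or NA when expression is unavailable).
#' @param hyper_status Rows of \code{\link{gene_hypermethylation}} for the
#'   gene (or NULL).
#' @param dac_responses Rows of \code{\link{dac_response}} for the gene (or
#'   NULL).
#' @param expression_cv One-row \code{\link{expression_cv}} result (or NULL).
#' @param summaries \code{\link{cpg_summaries}} output for the normal cohort.
#' @param map A \code{probe_gene_map}.
#' @param config An \code{analysis_config}.
#' @return List of class \code{evidence_bundle}.
#' @export
evidence_bundle <- function(gene, variability = NULL, inverse_correlated = NA,
                            hyper_status = NULL, dac_responses = NULL,
                            expression_cv = NULL, summaries = NULL,
                            map = NULL, config = analysis_config()) {
  five_prime_medians <- body_medians <- numeric(0)
  if (!is.null(summaries) && !is.null(map)) {
    p5 <- gene_probes(map, gene, config$region_set_5prime)
    pb <- gene_probes(map, gene, "BODY")
    five_prime_medians <- summaries$median[match(p5$probe_id, summaries$probe_id)]
    body_medians <- summaries$median[match(pb$probe_id, summaries$probe_id)]
    five_prime_medians <- five_prime_medians[!is.na(five_prime_medians)]
    body_medians <- body_medians[!is.na(body_medians)]
  }
  hyper_lines <- if (!is.null(hyper_status))
    hyper_status$cell_line[hyper_status$hypermethylated] else character(0)
  dac_lines <- if (!is.null(dac_responses))
    dac_responses$cell_line[dac_responses$responsive %in% TRUE] else character(0)
  structure(list(
    gene = gene,
    max_beta_r = if (!is.null(variability) && isTRUE(variability$scored))
      variability$max_beta_r else NA_real_,
    inverse_correlated = inverse_correlated,
    tumor_hyper_lines = hyper_lines,
    dac_responsive_lines = dac_lines,
    expression_cv = if (!is.null(expression_cv) && isTRUE(expression_cv$defined))
      expression_cv$cv_percent else NA_real_,
    five_prime_medians = five_prime_medians,
    body_medians = body_medians
  ), class = "evidence_bundle")
}

#' Classify one gene's methylation landscape
#'
#' Rules, evaluated with precedence HVM > TSG > HKG:
#' \itemize{
#'   \item HVM — max beta_R strictly above the variability threshold AND an
#'     inverse methylation-expression correlation.
#'   \item TSG — stable in normals (max beta_R at or below the threshold)
#'     AND some cell line is both hypermethylated in the 5' region and
#'     demethylation-responsive.
#'   \item HKG — stable in normals, every 5' regulatory median beta at or
#'     below \code{hkg_low_beta}, at least one gene-body median beta at or
#'     above \code{hkg_high_body_beta}, and expression CV at or below the
#'     housekeeping CV threshold.
#'   \item otherwise UNCLASSIFIED.
#' }
#' Unevaluable criteria (missing evidence) fail closed: they never satisfy
#' a rule, and are recorded in the rule trace.
#'
#' @param ev An \code{evidence_bundle}.
#' @param theta_var Variability threshold (max control beta_R).
#' @param theta_cv Expression-stability threshold (max control CV percent).
#' @param config An \code{analysis_config}.
#' @return One-row data.frame: gene, label, rule_trace (semicolon-joined).
#' @export
classify_gene <- function(ev, theta_var, theta_cv, config = analysis_config()) {
  trace <- character(0)
  note <- function(ok, what) {
    trace <<- c(trace, paste0(what, "=", if (is.na(ok)) "unevaluable" else ok))
    isTRUE(ok)
  }
  variable <- if (is.na(ev$max_beta_r)) NA else ev$max_beta_r > theta_var
  stable <- if (is.na(ev$max_beta_r)) NA else !variable
  inv <- ev$inverse_correlated
  hvm <- note(variable, "beta_r_above_threshold") & note(inv, "inverse_correlated")
  if (isTRUE(hvm)) {
    return(data.frame(gene = ev$gene, label = "HVM",
                      rule_trace = paste(trace, collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  same_line <- length(intersect(ev$tumor_hyper_lines, ev$dac_responsive_lines)) > 0
  tsg <- note(stable, "stable_in_normals") &
    note(same_line, "hyper_and_responsive_same_line")
  if (isTRUE(tsg)) {
    return(data.frame(gene = ev$gene, label = "TSG",
                      rule_trace = paste(trace, collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  low5 <- if (length(ev$five_prime_medians) == 0) NA else
    all(ev$five_prime_medians <= config$hkg_low_beta)
  hibody <- if (length(ev$body_medians) == 0) NA else
    any(ev$body_medians >= config$hkg_high_body_beta)
  stable_expr <- if (is.na(ev$expression_cv) || is.na(theta_cv)) NA else
    ev$expression_cv <= theta_cv
  hkg <- isTRUE(stable) & note(low5, "hypomethylated_5prime") &
    note(hibody, "hypermethylated_body") & note(stable_expr, "stable_expression")
  label <- if (isTRUE(hkg)) "HKG" else "UNCLASSIFIED"
  data.frame(gene = ev$gene, label = label,
             rule_trace = paste(trace, collapse = ";"), stringsAsFactors = FALSE)
}

#' Classify a whole panel
#'
#' @param bundles List of \code{evidence_bundle} objects.
#' @param theta_var,theta_cv Derived thresholds.
#' @param config An \code{analysis_config}.
#' @return List: \code{table} (gene, label, rule_trace) and \code{counts}
#'   (named integer vector over HVM/TSG/HKG/UNCLASSIFIED).
#' @export
classify_panel <- function(bundles, theta_var, theta_cv,
                           config = analysis_config()) {
  tab <- do.call(rbind, lapply(bundles, classify_gene,
                               theta_var = theta_var, theta_cv = theta_cv,
                               config = config))
  rownames(tab) <- NULL
  lv <- c("HVM", "TSG", "HKG", "UNCLASSIFIED")
  counts <- table(factor(tab$label, levels = lv))
  list(table = tab, counts = stats::setNames(as.integer(counts), lv))
}
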