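#' Per-CpG box statistics and the beta_R range statistic
#'
#' For each probe, computes min, quartiles (type-7 linear interpolation),
#' median, max and the inter-individual variability statistic
#' beta_R = max - min over the selected samples. Missing values are dropped
#' per probe; probes with fewer than two usable values are excluded and
#' listed in the \code{insufficient_probes} attribute.
#'
#' @param beta A \code{beta_matrix}.
#' @param sample_ids Samples to use; default all columns.
#' @return data.frame with columns probe_id, n, min, q1, median, q3, max,
#'   beta_r.
#' @export
cpg_summaries <- function(beta, sample_ids = NULL) {
  m <- beta$values
  if (!is.null(sample_ids)) {
    missing_s <- setdiff(sample_ids, colnames(m))
    if (length(missing_s))
      stop("sample(s) not in beta matrix: ", paste(missing_s, collapse = ", "))
    m <- m[, sample_ids, drop = FALSE]
  }
  n <- rowSums(!is.na(m))
  ok <- n >= 2
  if (any(!ok))
    warning(sum(!ok), " probe(s) with <2 usable values excluded")
  mm <- m[ok, , drop = FALSE]
  qs <- t(apply(mm, 1, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, type = 7))
  out <- data.frame(
    probe_id = rownames(mm),
    n = n[ok],
    min = qs[, 1], q1 = qs[, 2], median = qs[, 3], q3 = qs[, 4], max = qs[, 5],
    beta_r = qs[, 5] - qs[, 1],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "insufficient_probes") <- rownames(m)[!ok]
  out
}

#' Gene-level maximum beta_R over the 5' regulatory region
#'
#' The degree of inter-individual methylation variability of a gene is the
#' single largest probe-level beta_R among its 5' regulatory probes (not an
#' average over the region). Ties are broken toward the 5'-most probe.
#'
#' @param summaries Output of \code{\link{cpg_summaries}}.
#' @param map A \code{probe_gene_map}.
#' @param gene Gene symbol.
#' @param region_set Region groups defining the 5' regulatory region.
#' @return One-row data.frame: gene, max_beta_r, argmax_probe,
#'   n_5prime_probes, scored (FALSE when the gene has no scored probe in the
#'   region set; then max_beta_r is NA).
#' @export
gene_max_beta_r <- function(summaries, map, gene,
                            region_set = c("TSS1500", "TSS200", "FIVE_UTR")) {
  probes <- gene_probes(map, gene, region_set)
  sub <- merge(probes, summaries, by = "probe_id")
  if (nrow(sub) == 0) {
    return(data.frame(gene = gene, max_beta_r = NA_real_,
                      argmax_probe = NA_character_, n_5prime_probes = 0L,
                      scored = FALSE, stringsAsFactors = FALSE))
  }
  sub <- sub[order(sub$gene_order), , drop = FALSE]
  i <- which(sub$beta_r == max(sub$beta_r))[1]  # 5'-most on ties
  data.frame(gene = gene, max_beta_r = sub$beta_r[i],
             argmax_probe = sub$probe_id[i],
             n_5prime_probes = nrow(sub), scored = TRUE,
             stringsAsFactors = FALSE)
}

#' Gene-level variability table for a set of genes
#' @inheritParams gene_max_beta_r
#' @param genes Gene symbols to score.
#' @return data.frame, one row per gene (see \code{\link{gene_max_beta_r}}).
#' @export
gene_variability_table <- function(summaries, map, genes,
                                   region_set = c("TSS1500", "TSS200", "FIVE_UTR")) {
  out <- do.call(rbind, lapply(genes, function(g)
    gene_max_beta_r(summaries, map, g, region_set)))
  rownames(out) <- NULL
  out
}

#' Control-gene-derived variability threshold
#'
#' The threshold above which a gene's methylation is called highly variable
#' is the largest max-beta_R observed among the control genes: "highly
#' variable" downstream means strictly greater than every control.
#'
#' @param control_variabilities data.frame from
#'   \code{\link{gene_variability_table}} on the control genes.
#' @return List with \code{value} and \code{source_genes}.
#' @export
derive_variability_threshold <- function(control_variabilities) {
  cv <- control_variabilities[control_variabilities$scored %in% TRUE, , drop = FALSE]
  if (nrow(cv) == 0) stop("no scored control genes; cannot derive threshold")
  list(value = max(cv$max_beta_r),
       source_genes = cv[, c("gene", "max_beta_r")])
}

#' Flag highly-variable-methylation (HVM) genes
#'
#' A gene is flagged iff its max beta_R exceeds the control-derived threshold
#' (strict inequality). Unscored genes (no 5' regulatory probes) are not
#' flagged and are reported separately in both denominators.
#'
#' @param panel_variabilities Gene variability table for the target panel.
#' @param threshold Threshold list from
#'   \code{\link{derive_variability_threshold}} or a bare numeric.
#' @return List: \code{table} (gene, max_beta_r, hvm_flag), \code{n_flagged},
#'   \code{n_scored}, \code{n_panel}, \code{fraction_scored},
#'   \code{fraction_panel}.
#' @export
flag_hvm_genes <- function(panel_variabilities, threshold) {
  thr <- if (is.list(threshold)) threshold$value else threshold
  tab <- panel_variabilities
  tab$hvm_flag <- tab$scored & !is.na(tab$max_beta_r) & tab$max_beta_r > thr
  n_flagged <- sum(tab$hvm_flag)
  n_scored <- sum(tab$scored)
  list(table = tab, threshold = thr, n_flagged = n_flagged,
       n_scored = n_scored, n_panel = nrow(tab),
       fraction_scored = if (n_scored > 0) n_flagged / n_scored else NA_real_,
       fraction_panel = if (nrow(tab) > 0) n_flagged / nrow(tab) else NA_real_)
}

#' Ordered methylation-map profile of one gene
#'
#' One row per probe in 5' to 3' order with box statistics, beta_R, a
#' 5'-regulatory-region indicator and a unique argmax marker — the tabular
#' form of a box-and-whisker methylation map, ready for plotting or TSV
#' export.
#'
#' @inheritParams gene_max_beta_r
#' @return data.frame with columns probe_id, position, region_group,
#'   min/q1/median/q3/max, beta_r, is_5prime, is_argmax.
#' @export
methylation_map_profile <- function(summaries, map, gene,
                                    region_set = c("TSS1500", "TSS200", "FIVE_UTR")) {
  probes <- gene_probes(map, gene)
  sub <- merge(probes, summaries, by = "probe_id")
  sub <- sub[order(sub$gene_order), , drop = FALSE]
  gv <- gene_max_beta_r(summaries, map, gene, region_set)
  out <- data.frame(
    probe_id = sub$probe_id, position = sub$position,
    region_group = sub$region_group,
    min = sub$min, q1 = sub$q1, median = sub$median, q3 = sub$q3,
    max = sub$max, beta_r = sub$beta_r,
    is_5prime = sub$region_group %in% region_set,
    is_argmax = !is.na(gv$argmax_probe) & sub$probe_id == gv$argmax_probe,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
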