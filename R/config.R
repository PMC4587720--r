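#' Region-group vocabulary
#'
#' Canonical region-group labels used throughout the package, in 5' to 3'
#' order of a typical gene model. Manifest spellings ("5'UTR", "1stExon",
#' "Body", "3'UTR") are mapped onto these tokens at parse time.
#'
#' @return Character vector of the six canonical region groups.
#' @export
region_groups <- function() {
  c("TSS1500", "TSS200", "FIVE_UTR", "FIRST_EXON", "BODY", "THREE_UTR")
}

# 450K manifest dialect -> canonical token. Unknown tokens are errors.
.region_dialect <- c(
  "TSS1500"  = "TSS1500",
  "TSS200"   = "TSS200",
  "5'UTR"    = "FIVE_UTR",
  "5UTR"     = "FIVE_UTR",
  "1stExon"  = "FIRST_EXON",
  "Body"     = "BODY",
  "3'UTR"    = "THREE_UTR",
  "3UTR"     = "THREE_UTR",
  "TSS1500"  = "TSS1500",
  "FIVE_UTR" = "FIVE_UTR",
  "FIRST_EXON" = "FIRST_EXON",
  "BODY"     = "BODY",
  "THREE_UTR" = "THREE_UTR"
)

map_region_token <- function(tokens) {
  out <- .region_dialect[tokens]
  bad <- is.na(out) & !is.na(tokens) & nzchar(tokens)
  if (any(bad)) {
    stop("Unknown region-group token(s): ",
         paste(unique(tokens[bad]), collapse = ", "))
  }
  unname(out)
}

#' Analysis configuration
#'
#' Holds the fixed analysis constants: the 5' regulatory region definition,
#' the tumor delta-beta cutoff, the demethylation fold-change cutoff, the
#' significance level, and the housekeeping-pattern beta thresholds.
#'
#' @param region_set_5prime Region groups forming the 5' regulatory region.
#'   Default \code{c("TSS1500","TSS200","FIVE_UTR")}.
#' @param delta_beta_cutoff Minimum beta difference (cell minus reference) for
#'   a hyper/hypomethylation call; strict inequality. Default 0.5.
#' @param fold_change_cutoff Minimum treated/control expression fold change
#'   for a demethylation response; strict inequality. Default 2.
#' @param alpha Significance level for correlation and signed-rank tests.
#'   Default 0.05.
#' @param hkg_low_beta Maximum 5' median beta for the housekeeping pattern.
#'   Default 0.3.
#' @param hkg_high_body_beta Minimum gene-body median beta for the
#'   housekeeping pattern. Default 0.7.
#' @param min_pairs_for_correlation Minimum complete pairs for a correlation
#'   test. Default 5.
#' @param tumor_call_mode \code{"difference"} (delta beta > cutoff) or
#'   \code{"absolute"} (cell beta > cutoff and reference beta <= cutoff).
#' @param one_sided_correlation If TRUE, the inverse-correlation p-value is
#'   one-sided (rho < 0); default FALSE (two-sided with sign requirement).
#' @param include_tsa If TRUE, TSA-only treated conditions count toward the
#'   demethylation response; default FALSE.
#' @param seed Integer seed recorded in run summaries.
#'
#' @return An object of class \code{analysis_config} (a validated list).
#' @export
analysis_config <- function(region_set_5prime = c("TSS1500", "TSS200", "FIVE_UTR"),
                            delta_beta_cutoff = 0.5,
                            fold_change_cutoff = 2.0,
                            alpha = 0.05,
                            hkg_low_beta = 0.3,
                            hkg_high_body_beta = 0.7,
                            min_pairs_for_correlation = 5L,
                            tumor_call_mode = c("difference", "absolute"),
                            one_sided_correlation = FALSE,
                            include_tsa = FALSE,
                            seed = 1L) {
  tumor_call_mode <- match.arg(tumor_call_mode)
  stopifnot(all(region_set_5prime %in% region_groups()))
  if (!(delta_beta_cutoff > 0 && delta_beta_cutoff < 1))
    stop("delta_beta_cutoff must be in (0, 1)")
  if (!(fold_change_cutoff > 1))
    stop("fold_change_cutoff must be > 1")
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)")
  structure(list(
    region_set_5prime = region_set_5prime,
    delta_beta_cutoff = delta_beta_cutoff,
    fold_change_cutoff = fold_change_cutoff,
    alpha = alpha,
    hkg_low_beta = hkg_low_beta,
    hkg_high_body_beta = hkg_high_body_beta,
    min_pairs_for_correlation = as.integer(min_pairs_for_correlation),
    tumor_call_mode = tumor_call_mode,
    one_sided_correlation = one_sided_correlation,
    include_tsa = include_tsa,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Gene panel definition
#'
#' A panel of target genes with family tags, plus the control gene lists used
#' to derive data-driven thresholds: methylation controls for the variability
#' threshold and expression controls (housekeeping genes) for the
#' expression-stability threshold.
#'
#' @param panel_genes data.frame with columns \code{gene} and \code{family}
#'   (e.g. CYP, GST, NAT, SULT, UGT, other).
#' @param control_methylation_genes Character vector; default the eight
#'   standard controls (four housekeeping, two tumor suppressor, two DNA
#'   repair genes).
#' @param control_expression_genes Character vector; default the housekeeping
#'   subset.
#' @param strand Optional named character vector gene -> "+"/"-" used to
#'   orient probes 5' to 3'; genes not listed default to "+".
#' @param isoform_loci Optional named list: locus -> data.frame with columns
#'   \code{isoform}, \code{transcript_tag}.
#'
#' @return An object of class \code{gene_panel}.
#' @export
gene_panel <- function(panel_genes,
                       control_methylation_genes = c("ACTB", "B2M", "GAPDH", "TBP",
                                                     "BMP4", "IGFBP3", "MLH1", "MGMT"),
                       control_expression_genes = c("ACTB", "B2M", "GAPDH", "TBP"),
                       strand = NULL,
                       isoform_loci = NULL) {
  panel_genes <- as.data.frame(panel_genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "family") %in% names(panel_genes)))
  if (anyDuplicated(panel_genes$gene))
    stop("duplicate gene symbols in panel_genes")
  if (anyDuplicated(control_methylation_genes) || anyDuplicated(control_expression_genes))
    stop("duplicate gene symbols in a control list")
  if (length(intersect(panel_genes$gene, control_methylation_genes)) ||
      length(intersect(panel_genes$gene, control_expression_genes)))
    stop("control gene lists must be disjoint from panel_genes")
  structure(list(
    panel_genes = panel_genes,
    control_methylation_genes = control_methylation_genes,
    control_expression_genes = control_expression_genes,
    strand = strand,
    isoform_loci = isoform_loci
  ), class = "gene_panel")
}

gene_strand <- function(panel, gene) {
  if (!is.null(panel$strand) && gene %in% names(panel$strand))
    panel$strand[[gene]] else "+"
}

#' All genes of a panel (targets plus controls)
#' @param panel A \code{gene_panel}.
#' @return Character vector of unique gene symbols.
#' @export
panel_all_genes <- function(panel) {
  unique(c(panel$panel_genes$gene,
           panel$control_methylation_genes,
           panel$control_expression_genes))
}

#' @export
print.gene_panel <- function(x, ...) {
  fam <- table(x$panel_genes$family)
  cat("gene_panel:", nrow(x$panel_genes), "target genes (",
      paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), ")\n")
  cat("  methylation controls:", paste(x$control_methylation_genes, collapse = ", "), "\n")
  cat("  expression controls: ", paste(x$control_expression_genes, collapse = ", "), "\n")
  if (!is.null(x$isoform_loci))
    cat("  isoform loci:", paste(names(x$isoform_loci), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}
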