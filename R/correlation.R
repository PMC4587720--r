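#' 75th-percentile normalization of an expression matrix
#'
#' Divides each sample column by its own 75th percentile (type-7 quantile),
#' the standard within-sample scaling for single-channel expression arrays.
#' Idempotent up to that rescaling: renormalizing a normalized matrix
#' returns it unchanged.
#'
#' @param expr An \code{expression_matrix}.
#' @return An \code{expression_matrix} with state \code{percentile75}.
#' @export
normalize_percentile75 <- function(expr) {
  m <- expr$values
  p75 <- apply(m, 2, stats::quantile, probs = 0.75, na.rm = TRUE, type = 7)
  zero <- names(p75)[!is.na(p75) & p75 == 0]
  if (length(zero))
    stop("75th percentile is 0 for sample(s): ", paste(zero, collapse = ", "))
  expression_matrix(sweep(m, 2, p75, "/"), normalization_state = "percentile75")
}

#' Express each gene relative to a reference gene (percent)
#'
#' Every value becomes 100 * value / reference-gene value in the same sample,
#' so the reference gene maps to 100 everywhere.
#'
#' @param expr An \code{expression_matrix}.
#' @param reference_gene Gene present with nonzero value in every sample.
#' @return An \code{expression_matrix} with state
#'   \code{reference_gene_percent}.
#' @export
relative_to_reference <- function(expr, reference_gene) {
  m <- expr$values
  if (!reference_gene %in% rownames(m))
    stop("reference gene '", reference_gene, "' not in expression matrix")
  ref <- m[reference_gene, ]
  bad <- colnames(m)[is.na(ref) | ref == 0]
  if (length(bad))
    stop("reference gene '", reference_gene, "' missing/zero in sample(s): ",
         paste(bad, collapse = ", "))
  expression_matrix(sweep(m, 2, ref, "/") * 100,
                    normalization_state = "reference_gene_percent")
}

#' Expression row representing a gene
#'
#' When several expression rows carry the same gene symbol (multi-probe
#' arrays), the row with the highest mean intensity represents the gene.
#'
#' @param expr An \code{expression_matrix}.
#' @param gene Gene symbol.
#' @param sample_ids Optional sample subset.
#' @return Named numeric vector of the gene's values, or NULL if absent.
#' @export
gene_expression_values <- function(expr, gene, sample_ids = NULL) {
  idx <- which(rownames(expr$values) == gene)
  if (!length(idx)) return(NULL)
  m <- expr$values[idx, , drop = FALSE]
  if (!is.null(sample_ids)) m <- m[, sample_ids, drop = FALSE]
  if (nrow(m) > 1) m <- m[which.max(rowMeans(m, na.rm = TRUE)), , drop = FALSE]
  stats::setNames(as.numeric(m[1, ]), colnames(m))
}

#' Expression coefficient of variation of a gene
#'
#' CV (percent) = 100 * sd / mean with the sample (n-1) standard deviation.
#' Flagged undefined when the mean is zero.
#'
#' @param expr An \code{expression_matrix}.
#' @param gene Gene symbol.
#' @param sample_ids Optional sample subset.
#' @return One-row data.frame: gene, n, mean, sd, cv_percent, defined.
#' @export
expression_cv <- function(expr, gene, sample_ids = NULL) {
  v <- gene_expression_values(expr, gene, sample_ids)
  if (is.null(v)) {
    return(data.frame(gene = gene, n = 0L, mean = NA_real_, sd = NA_real_,
                      cv_percent = NA_real_, defined = FALSE,
                      stringsAsFactors = FALSE))
  }
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("expression_cv needs >= 2 samples for gene ", gene)
  mu <- mean(v)
  sdv <- stats::sd(v)
  defined <- mu != 0
  data.frame(gene = gene, n = length(v), mean = mu, sd = sdv,
             cv_percent = if (defined) 100 * sdv / mu else NA_real_,
             defined = defined, stringsAsFactors = FALSE)
}

#' Expression-stability threshold from housekeeping controls
#'
#' The threshold is the largest CV (percent) among the control expression
#' genes; panel genes with CV above it are considered variably expressed.
#'
#' @param control_summaries data.frame of \code{\link{expression_cv}} rows
#'   for the control genes.
#' @return Numeric threshold.
#' @export
derive_cv_threshold <- function(control_summaries) {
  cs <- control_summaries[control_summaries$defined %in% TRUE, , drop = FALSE]
  if (nrow(cs) == 0) stop("no defined control CVs; cannot derive threshold")
  max(cs$cv_percent)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks (tie-handled); the
#' two-sided p-value uses the t approximation with n-2 degrees of freedom.
#' With |rho| = 1 the t statistic is unbounded and the p-value is reported
#' as the smallest representable positive double, flagged via
#' \code{p_floored}. Constant input leaves rho undefined (degenerate flag).
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @param one_sided If TRUE, p is the one-sided lower-tail (rho < 0) value.
#' @return List: rho, p_value, n_pairs, degenerate, p_floored.
#' @export
spearman_rho_p <- function(x, y, one_sided = FALSE) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_pairs = n,
                degenerate = TRUE, p_floored = FALSE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15 && abs(rho) <= 1) {
    p <- .Machine$double.xmin
    if (one_sided && rho > 0) p <- 1
    return(list(rho = rho, p_value = p, n_pairs = n,
                degenerate = FALSE, p_floored = !(one_sided && rho > 0)))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (one_sided) stats::pt(tstat, df = n - 2)
       else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = min(p, 1), n_pairs = n,
       degenerate = FALSE, p_floored = FALSE)
}

#' Per-CpG methylation-expression correlation for one gene
#'
#' Tests every 5' regulatory probe of the gene for rank correlation between
#' its beta values and the gene's expression across the matched samples.
#' A probe is \code{inverse_significant} iff rho < 0 and p < alpha; the gene
#' is called inverse-correlated iff at least one probe is. When probe-level
#' beta_R values and the variability threshold are supplied,
#' \code{hvm_overlap} marks probes that are simultaneously inverse-
#' significant and more variable than the threshold.
#'
#' @param gene Gene symbol.
#' @param beta A \code{beta_matrix}.
#' @param expr An \code{expression_matrix} (normalized).
#' @param map A \code{probe_gene_map}.
#' @param config An \code{analysis_config}.
#' @param summaries Optional \code{\link{cpg_summaries}} output carrying
#'   beta_R per probe (typically from the full variability cohort).
#' @param variability_threshold Optional numeric threshold for hvm_overlap.
#' @param sample_ids Optional explicit matched sample set; default the
#'   intersection of beta and expression samples.
#' @return data.frame, one row per tested probe: gene, probe_id, n_pairs,
#'   rho, p_value, inverse_significant, beta_r, hvm_overlap; attribute
#'   \code{gene_inverse_correlated}.
#' @export
correlate_gene <- function(gene, beta, expr, map, config = analysis_config(),
                           summaries = NULL, variability_threshold = NULL,
                           sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- intersect(colnames(beta$values), colnames(expr$values))
  if (length(sample_ids) == 0)
    stop("no matched samples between beta and expression matrices")
  ev <- gene_expression_values(expr, gene, sample_ids)
  probes <- gene_probes(map, gene, config$region_set_5prime)
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    pid <- probes$probe_id[i]
    if (!pid %in% rownames(beta$values)) next
    bv <- beta$values[pid, sample_ids]
    keep <- !is.na(bv) & !is.na(ev)
    if (sum(keep) < config$min_pairs_for_correlation) next
    sp <- spearman_rho_p(bv[keep], ev[keep],
                         one_sided = config$one_sided_correlation)
    inv <- !sp$degenerate && !is.na(sp$rho) && sp$rho < 0 &&
      sp$p_value < config$alpha
    br <- if (!is.null(summaries)) {
      j <- match(pid, summaries$probe_id)
      if (is.na(j)) NA_real_ else summaries$beta_r[j]
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, probe_id = pid, n_pairs = sp$n_pairs,
      rho = sp$rho, p_value = sp$p_value, inverse_significant = inv,
      beta_r = br,
      hvm_overlap = inv && !is.na(br) && !is.null(variability_threshold) &&
        br > variability_threshold,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), probe_id = character(0),
               n_pairs = integer(0), rho = numeric(0), p_value = numeric(0),
               inverse_significant = logical(0), beta_r = numeric(0),
               hvm_overlap = logical(0))
  rownames(out) <- NULL
  attr(out, "gene_inverse_correlated") <- any(out$inverse_significant)
  out
}
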