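#' Exact one-sample Wilcoxon signed-rank test against a fixed reference
#'
#' Tests whether a cohort of values is symmetrically distributed around a
#' fixed reference value. Zero differences are dropped; tied absolute
#' differences receive average ranks. For n at most \code{exact_max_n} the
#' two-sided p-value is exact, from the full distribution of the
#' positive-rank sum over all 2^n sign assignments (computed by
#' convolution, identical to explicit enumeration); above that, a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. The reference is treated as fixed, not as a random draw.
#'
#' @param cohort_betas Numeric cohort values (e.g. 18 liver beta values).
#' @param reference_value Single fixed reference (e.g. one intestine beta).
#' @param exact_max_n Largest n for the exact distribution; default 25.
#' @return List: statistic (positive-rank sum W), n (nonzero differences),
#'   p_value, direction ("reference_higher" when the cohort sits below the
#'   reference, "reference_lower" when above, "none"), exact flag.
#' @export
wilcoxon_one_sample <- function(cohort_betas, reference_value,
                                exact_max_n = 25L) {
  d <- cohort_betas[!is.na(cohort_betas)] - reference_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n = 0L, p_value = 1,
                direction = "none", exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max_n) {
    # doubled ranks are integers even with .5 average ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1)   # cnt[s+1] = #sign assignments with 2W = s
    cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[seq_len(total + 1 - rr)])
      cnt <- cnt + shifted
    }
    w2 <- as.integer(round(2 * W))
    p_le <- sum(cnt[seq_len(w2 + 1)]) / 2^n
    p_ge <- sum(cnt[(w2 + 1):(total + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  direction <- if (W < mu) "reference_higher" else
    if (W > mu) "reference_lower" else "none"
  list(statistic = W, n = n, p_value = p, direction = direction, exact = exact)
}

#' Classify an isoform as hepatic or intestinal by dominant expression
#'
#' Hepatic iff the liver mean exceeds the intestine mean; an explicit
#' per-isoform override may force the class (flagged), mirroring curation of
#' isoforms with substantial expression in both tissues. Equal means demand
#' an override.
#'
#' @param tissue_means Named numeric vector with elements \code{liver} and
#'   \code{intestine} (mean normalized expression).
#' @param isoform Isoform name.
#' @param override Optional "hepatic" or "intestinal".
#' @return One-row data.frame: isoform, liver_mean, intestine_mean,
#'   tissue_class, override_applied.
#' @export
classify_isoform_tissue <- function(tissue_means, isoform, override = NULL) {
  stopifnot(all(c("liver", "intestine") %in% names(tissue_means)))
  lv <- tissue_means[["liver"]]; iv <- tissue_means[["intestine"]]
  if (!is.null(override)) {
    override <- match.arg(override, c("hepatic", "intestinal"))
    cls <- override; ov <- TRUE
  } else if (lv == iv) {
    stop("equal liver/intestine means for isoform ", isoform,
         ": an explicit override is required")
  } else {
    cls <- if (lv > iv) "hepatic" else "intestinal"; ov <- FALSE
  }
  data.frame(isoform = isoform, liver_mean = lv, intestine_mean = iv,
             tissue_class = cls, override_applied = ov,
             stringsAsFactors = FALSE)
}

#' First-exon-region probes of an isoform
#'
#' Probes annotated to the isoform's transcript in the TSS200, 5'UTR or
#' first-exon groups, in 5' to 3' order; the more distal TSS1500 probes are
#' excluded by default.
#'
#' @param map A \code{probe_gene_map} whose rows carry transcript tags.
#' @param transcript_tag The isoform's transcript tag.
#' @param include_tss1500 Include TSS1500 probes as well; default FALSE.
#' @return The matching map rows, ordered 5' to 3'.
#' @export
first_exon_probes <- function(map, transcript_tag, include_tss1500 = FALSE) {
  regions <- c("TSS200", "FIVE_UTR", "FIRST_EXON")
  if (include_tss1500) regions <- c("TSS1500", regions)
  sub <- map[!is.na(map$transcript_tag) & map$transcript_tag == transcript_tag &
               map$region_group %in% regions, , drop = FALSE]
  sub[order(sub$gene_order), , drop = FALSE]
}

#' Most proximal retained probe of an isoform
#'
#' The retained first-exon-region probe closest to the transcription start
#' site, i.e. the 5'-most of \code{\link{first_exon_probes}}.
#'
#' @inheritParams first_exon_probes
#' @return One map row, or NULL when no probe is retained.
#' @export
most_proximal_probe <- function(map, transcript_tag, include_tss1500 = FALSE) {
  sub <- first_exon_probes(map, transcript_tag, include_tss1500)
  if (nrow(sub) == 0) return(NULL)
  sub[1, , drop = FALSE]
}

#' Concordance between first-exon methylation and tissue-dominant expression
#'
#' For each isoform, the most proximal first-exon probe's beta values in the
#' liver cohort are tested against the single reference-tissue value with
#' the exact signed-rank test. A hepatic isoform is concordant when the
#' reference (intestine) is significantly more methylated than the liver
#' cohort; an intestinal isoform when the liver cohort is significantly more
#' methylated than the reference.
#'
#' @param tissue_calls data.frame of \code{\link{classify_isoform_tissue}}
#'   rows.
#' @param beta A \code{beta_matrix} containing the liver cohort and the
#'   reference sample.
#' @param map A \code{probe_gene_map} with transcript tags.
#' @param isoforms data.frame with columns isoform, transcript_tag.
#' @param cohort_samples Liver cohort sample IDs.
#' @param reference_sample Reference tissue sample ID (e.g. the intestine).
#' @param config An \code{analysis_config} (alpha).
#' @return data.frame, one row per testable isoform: isoform, tissue_class,
#'   probe_id, n, cohort_median, reference_beta, statistic, p_value,
#'   direction, concordant. Isoforms with no retained probe are omitted and
#'   listed in the \code{untested_isoforms} attribute.
#' @export
isoform_concordance <- function(tissue_calls, beta, map, isoforms,
                                cohort_samples, reference_sample,
                                config = analysis_config()) {
  rows <- list(); untested <- character(0)
  for (i in seq_len(nrow(isoforms))) {
    iso <- isoforms$isoform[i]
    probe <- most_proximal_probe(map, isoforms$transcript_tag[i])
    if (is.null(probe) || !probe$probe_id %in% rownames(beta$values)) {
      untested <- c(untested, iso)
      next
    }
    cohort <- beta$values[probe$probe_id, cohort_samples]
    refb <- beta$values[probe$probe_id, reference_sample]
    wt <- wilcoxon_one_sample(cohort[!is.na(cohort)], refb)
    cls <- tissue_calls$tissue_class[match(iso, tissue_calls$isoform)]
    concordant <- wt$p_value < config$alpha &&
      ((cls == "hepatic" && wt$direction == "reference_higher") ||
         (cls == "intestinal" && wt$direction == "reference_lower"))
    rows[[length(rows) + 1L]] <- data.frame(
      isoform = iso, tissue_class = cls, probe_id = probe$probe_id,
      n = wt$n, cohort_median = stats::median(cohort, na.rm = TRUE),
      reference_beta = unname(refb), statistic = wt$statistic,
      p_value = wt$p_value, direction = wt$direction,
      concordant = concordant, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(isoform = character(0), tissue_class = character(0),
               probe_id = character(0), n = integer(0),
               cohort_median = numeric(0), reference_beta = numeric(0),
               statistic = numeric(0), p_value = numeric(0),
               direction = character(0), concordant = logical(0))
  rownames(out) <- NULL
  attr(out, "untested_isoforms") <- untested
  out
}

#' Shared-locus isoform analysis driver
#'
#' Classifies each isoform of a shared-first-exon locus by tissue-dominant
#' expression (with explicit overrides), then tests first-exon methylation
#' concordance against a reference tissue sample.
#'
#' @param beta A \code{beta_matrix} (liver cohort + reference sample(s)).
#' @param map A \code{probe_gene_map} with transcript tags.
#' @param isoforms data.frame with columns isoform, transcript_tag.
#' @param tissue_expression data.frame with columns isoform, liver_mean,
#'   intestine_mean.
#' @param cohort_samples Liver cohort sample IDs.
#' @param reference_sample Reference sample ID.
#' @param overrides Optional named character vector isoform -> class.
#' @param config An \code{analysis_config}.
#' @return List: \code{tissue_calls}, \code{concordance}.
#' @export
analyze_isoform_locus <- function(beta, map, isoforms, tissue_expression,
                                  cohort_samples, reference_sample,
                                  overrides = NULL,
                                  config = analysis_config()) {
  calls <- do.call(rbind, lapply(seq_len(nrow(tissue_expression)), function(i) {
    iso <- tissue_expression$isoform[i]
    classify_isoform_tissue(
      c(liver = tissue_expression$liver_mean[i],
        intestine = tissue_expression$intestine_mean[i]),
      iso,
      override = if (!is.null(overrides) && iso %in% names(overrides))
        overrides[[iso]] else NULL)
  }))
  conc <- isoform_concordance(calls, beta, map, isoforms, cohort_samples,
                              reference_sample, config)
  list(tissue_calls = calls, concordance = conc)
}
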