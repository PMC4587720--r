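test_that("exact signed-rank p-values match hand-enumerated cases", {
  w <- wilcoxon_one_sample(c(0.1, 0.2, 0.3, 0.4, 0.5), 0.6)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 32)              # 0.0625 by 2^5 enumeration
  expect_equal(w$direction, "reference_higher")
  expect_true(w$exact)
  # n = 18, reference far above the cohort maximum
  w18 <- wilcoxon_one_sample(seq(0.01, 0.18, by = 0.01), 0.9)
  expect_equal(w18$p_value, 2 / 2^18)
  # all differences zero
  w0 <- wilcoxon_one_sample(rep(0.4, 6), 0.4)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$direction, "none")
  # symmetric cohort around the reference: p near 1
  ws <- wilcoxon_one_sample(c(0.3, 0.5, 0.2, 0.6, 0.35, 0.45), 0.4)
  expect_gt(ws$p_value, 0.5)
})

test_that("exact p equals full 2^n enumeration for n <= 12, ties included", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(5:12, 1)
    cohort <- if (rep %% 2) runif(n) else
      sample(seq(0.05, 0.5, by = 0.05), n, replace = TRUE)  # forces ties
    ref <- sample(seq(0.05, 0.6, by = 0.05), 1)
    o <- oracle_wilcoxon(cohort, ref)
    w <- wilcoxon_one_sample(cohort, ref)
    expect_equal(w$statistic, o$W)
    expect_equal(w$p_value, o$p, tolerance = 1e-12)
  }
})

test_that("signed-rank test agrees with wilcox.test on tie-free data", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(c(6:20), 1)
    cohort <- runif(n); ref <- runif(1)
    w <- wilcoxon_one_sample(cohort, ref)
    bw <- suppressWarnings(wilcox.test(cohort, mu = ref, exact = TRUE,
                                       correct = TRUE))
    expect_equal(w$statistic, unname(bw$statistic))
    expect_equal(w$p_value, bw$p.value, tolerance = 1e-10)
  }
})

test_that("signed-rank p is shift-invariant and reflection-symmetric", {
  set.seed(8)
  for (rep in 1:20) {
    cohort <- runif(10); ref <- 0.5
    w <- wilcoxon_one_sample(cohort, ref)
    shifted <- wilcoxon_one_sample(cohort + 0.2, ref + 0.2)
    expect_equal(shifted$statistic, w$statistic)
    expect_equal(shifted$p_value, w$p_value)
    mirrored <- wilcoxon_one_sample(2 * ref - cohort, ref)
    expect_equal(mirrored$p_value, w$p_value)
    expect_equal(mirrored$statistic, 10 * 11 / 2 - w$statistic)
  }
})

test_that("large cohorts switch to the tie-corrected normal approximation", {
  set.seed(9)
  cohort <- runif(40, 0.2, 0.4)
  w <- wilcoxon_one_sample(cohort, 0.5)
  expect_false(w$exact)
  bw <- suppressWarnings(wilcox.test(cohort, mu = 0.5, exact = FALSE,
                                     correct = TRUE))
  expect_equal(w$p_value, bw$p.value, tolerance = 1e-10)
})

test_that("tissue classification follows dominance with explicit overrides", {
  h <- classify_isoform_tissue(c(liver = 10, intestine = 1), "UGT1A1")
  expect_equal(h$tissue_class, "hepatic")
  expect_false(h$override_applied)
  i <- classify_isoform_tissue(c(liver = 1, intestine = 10), "UGT1A10")
  expect_equal(i$tissue_class, "intestinal")
  # the curated exception: liver signal higher, forced intestinal
  o <- classify_isoform_tissue(c(liver = 12, intestine = 9), "UGT1A8",
                               override = "intestinal")
  expect_equal(o$tissue_class, "intestinal")
  expect_true(o$override_applied)
  expect_error(classify_isoform_tissue(c(liver = 5, intestine = 5), "X"),
               "override")
})

iso_map <- function() {
  df <- data.frame(
    probe_id = paste0("p", 1:4), gene = "LOC",
    region_group = c("TSS1500", "TSS200", "FIRST_EXON", "BODY"),
    transcript_tag = c("NM_A", "NM_A", "NM_A", "NM_A"),
    chromosome = "2", position = c(10L, 20L, 30L, 40L), gene_order = 1:4)
  class(df) <- c("probe_gene_map", "data.frame")
  df
}

test_that("first-exon probe selection excludes TSS1500 and finds the proximal probe", {
  fe <- first_exon_probes(iso_map(), "NM_A")
  expect_equal(fe$probe_id, c("p2", "p3"))     # TSS1500 and body excluded
  expect_equal(most_proximal_probe(iso_map(), "NM_A")$probe_id, "p2")
  # union with TSS1500 recovers all 5' probes of the transcript (no loss)
  fe_all <- first_exon_probes(iso_map(), "NM_A", include_tss1500 = TRUE)
  expect_equal(fe_all$probe_id, c("p1", "p2", "p3"))
  expect_null(most_proximal_probe(iso_map(), "NM_NOPE"))
})

test_that("concordance pairs methylation direction with tissue class", {
  loc <- generate_isoform_locus(seed = 5)
  cohort <- samples_in_group(loc$beta, "adult_liver")
  res <- analyze_isoform_locus(loc$beta, loc$map, loc$isoforms,
                               loc$tissue_expression, cohort, "NSI")
  got <- setNames(res$concordance$concordant, res$concordance$isoform)
  expect_equal(got[names(loc$truth)], loc$truth)
  # hepatic concordant isoforms: cohort below the intestinal reference
  hep <- res$concordance[res$concordance$tissue_class == "hepatic" &
                           res$concordance$concordant, ]
  expect_true(all(hep$cohort_median < hep$reference_beta))
  expect_true(all(hep$direction == "reference_higher"))
})

test_that("fetal-liver comparisons reuse the same machinery", {
  loc <- generate_isoform_locus(seed = 6)
  cohort <- samples_in_group(loc$beta, "adult_liver")
  calls <- do.call(rbind, lapply(seq_len(nrow(loc$tissue_expression)), function(i)
    classify_isoform_tissue(c(liver = loc$tissue_expression$liver_mean[i],
                              intestine = loc$tissue_expression$intestine_mean[i]),
                            loc$tissue_expression$isoform[i])))
  res <- isoform_concordance(calls, loc$beta, loc$map, loc$isoforms,
                             cohort, "NLF")
  hep <- res[res$tissue_class == "hepatic" & res$isoform %in%
               names(loc$truth)[loc$truth], ]
  # planted age effect: fetal liver more methylated than the adult cohort
  expect_true(all(hep$direction == "reference_higher"))
  expect_true(all(hep$p_value < 0.05))
})
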