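test_that("per-CpG summaries give box statistics and beta_R = max - min", {
  m <- rbind(cg1 = c(0.4, 0.4, 0.4), cg2 = c(0.1, 0.4, 0.35),
             cg3 = c(0.0, 1.0, NA))
  colnames(m) <- paste0("S", 1:3)
  s <- cpg_summaries(beta_matrix(m))
  expect_equal(unlist(s[s$probe_id == "cg1", c("min", "q1", "median", "q3", "max")]),
               rep(0.4, 5), ignore_attr = TRUE)
  expect_equal(s$beta_r[s$probe_id == "cg1"], 0)
  expect_equal(s$beta_r[s$probe_id == "cg2"], 0.30)
  expect_equal(s$beta_r[s$probe_id == "cg3"], 1.0)   # missing dropped pairwise
  expect_equal(s$n[s$probe_id == "cg3"], 2L)

  m2 <- rbind(cg1 = c(0.2, 0.3), cg2 = c(0.5, NA))
  colnames(m2) <- c("S1", "S2")
  expect_warning(s2 <- cpg_summaries(beta_matrix(m2)), "excluded")
  expect_identical(attr(s2, "insufficient_probes"), "cg2")
})

test_that("beta_R matches brute force and is sample-permutation invariant", {
  set.seed(42)
  for (rep in 1:50) {
    v <- runif(sample(3:20, 1))
    m <- matrix(v, 1, dimnames = list("p", paste0("S", seq_along(v))))
    s <- cpg_summaries(beta_matrix(m))
    expect_equal(s$beta_r, max(v) - min(v))
    perm <- sample(seq_along(v))
    mp <- m[, perm, drop = FALSE]
    expect_equal(cpg_summaries(beta_matrix(mp))$beta_r, s$beta_r)
  }
})

test_that("adding samples never decreases beta_R", {
  set.seed(7)
  for (rep in 1:20) {
    v <- runif(10)
    m1 <- matrix(v[1:6], 1, dimnames = list("p", paste0("S", 1:6)))
    m2 <- matrix(v, 1, dimnames = list("p", paste0("S", 1:10)))
    expect_gte(cpg_summaries(beta_matrix(m2))$beta_r,
               cpg_summaries(beta_matrix(m1))$beta_r)
  }
})

make_map <- function(df) { class(df) <- c("probe_gene_map", "data.frame"); df }

test_that("gene-level maximum beta_R uses 5' probes with 5'-most tie-break", {
  map <- make_map(data.frame(
    probe_id = c("p1", "p2", "p3", "p4"), gene = "G",
    region_group = c("TSS1500", "TSS200", "FIVE_UTR", "BODY"),
    transcript_tag = NA, chromosome = "1",
    position = c(10L, 20L, 30L, 40L), gene_order = 1:4))
  s <- data.frame(probe_id = c("p1", "p2", "p3", "p4"), n = 5L,
                  min = 0, q1 = 0, median = 0, q3 = 0, max = 0,
                  beta_r = c(0.05, 0.31, 0.12, 0.9))
  gv <- gene_max_beta_r(s, map, "G")
  expect_equal(gv$max_beta_r, 0.31)           # body probe 0.9 is ignored
  expect_equal(gv$argmax_probe, "p2")
  expect_equal(gv$n_5prime_probes, 3L)

  s$beta_r <- c(0.31, 0.31, 0.12, 0.9)        # tie -> 5'-most probe
  expect_equal(gene_max_beta_r(s, map, "G")$argmax_probe, "p1")

  body_only <- make_map(map[map$region_group == "BODY", ])
  gv2 <- gene_max_beta_r(s, body_only, "G")
  expect_false(gv2$scored)
  expect_true(is.na(gv2$max_beta_r))
})

test_that("variability threshold is the control maximum and grows monotonically", {
  cv <- data.frame(gene = c("c1", "c2", "c3"),
                   max_beta_r = c(0.10, 0.296, 0.22),
                   argmax_probe = "p", n_5prime_probes = 1L, scored = TRUE)
  expect_equal(derive_variability_threshold(cv)$value, 0.296)
  expect_equal(derive_variability_threshold(cv[1, ])$value, 0.10)
  expect_error(derive_variability_threshold(cv[0, ]), "no scored control")
  # adding a control can never decrease the threshold
  set.seed(11)
  for (rep in 1:20) {
    base <- cv[sample(3, 2), ]
    extra <- rbind(base, data.frame(gene = "cx", max_beta_r = runif(1),
                                    argmax_probe = "p", n_5prime_probes = 1L,
                                    scored = TRUE))
    expect_gte(derive_variability_threshold(extra)$value,
               derive_variability_threshold(base)$value)
  }
})

test_that("HVM flagging is strict and non-increasing in the threshold", {
  pv <- data.frame(gene = letters[1:4], max_beta_r = c(0.296, 0.40, 0.10, NA),
                   argmax_probe = "p", n_5prime_probes = c(1L, 1L, 1L, 0L),
                   scored = c(TRUE, TRUE, TRUE, FALSE))
  fl <- flag_hvm_genes(pv, 0.296)
  expect_false(fl$table$hvm_flag[1])          # equality is NOT flagged
  expect_true(fl$table$hvm_flag[2])
  expect_equal(fl$n_flagged, 1L)
  expect_equal(fl$n_scored, 3L)
  counts <- vapply(seq(0, 1, by = 0.05),
                   function(t) flag_hvm_genes(pv, t)$n_flagged, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("methylation map profiles are ordered 5' to 3' with one argmax row", {
  map <- make_map(data.frame(
    probe_id = paste0("p", 1:4), gene = "G",
    region_group = c("TSS200", "FIVE_UTR", "BODY", "THREE_UTR"),
    transcript_tag = NA, chromosome = "1",
    position = c(5L, 10L, 20L, 30L), gene_order = 1:4))
  m <- matrix(c(0.1, 0.2, 0.15, 0.6, 0.12, 0.8, 0.82, 0.81), 4, 2,
              dimnames = list(paste0("p", 1:4), c("S1", "S2")))
  prof <- methylation_map_profile(cpg_summaries(beta_matrix(m)), map, "G")
  expect_equal(prof$probe_id, paste0("p", 1:4))
  expect_equal(sum(prof$is_argmax), 1L)
  expect_equal(prof$probe_id[prof$is_argmax], "p2")
  expect_equal(prof$is_5prime, c(TRUE, TRUE, FALSE, FALSE))
  # constant-beta gene: beta_r = 0 on every row
  mc <- matrix(0.4, 4, 2, dimnames = dimnames(m))
  profc <- methylation_map_profile(cpg_summaries(beta_matrix(mc)), map, "G")
  expect_true(all(profc$beta_r == 0))
})
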