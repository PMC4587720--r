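tumor_beta <- function() {
  m <- rbind(p1 = c(0.9, 0.1), p2 = c(0.6, 0.1), p3 = c(0.05, 0.8),
             p4 = c(NA, 0.5))
  colnames(m) <- c("HepG2", "NL2")
  beta_matrix(m)
}

test_that("differential calls apply strict delta-beta cutoffs", {
  calls <- differential_calls(tumor_beta(), "HepG2", "NL2")
  expect_equal(calls$direction[calls$probe_id == "p1"], "hyper")   # +0.8
  expect_equal(calls$direction[calls$probe_id == "p2"], "none")    # +0.5 strict
  expect_equal(calls$direction[calls$probe_id == "p3"], "hypo")    # -0.75
  expect_false("p4" %in% calls$probe_id)       # pairwise-complete only
  expect_error(differential_calls(tumor_beta(), "HepG2", "NOPE"), "NOPE")
})

test_that("direction is antisymmetric under swapping cell and reference", {
  set.seed(21)
  m <- matrix(runif(40), 20, 2, dimnames = list(paste0("p", 1:20), c("A", "B")))
  b <- beta_matrix(m)
  fwd <- differential_calls(b, "A", "B")
  rev <- differential_calls(b, "B", "A")
  swap <- c(hyper = "hypo", hypo = "hyper", none = "none")
  expect_equal(rev$direction, unname(swap[fwd$direction]))
  expect_equal(rev$delta_beta, -fwd$delta_beta)
})

test_that("absolute-level call mode uses the configured level rule", {
  calls <- differential_calls(tumor_beta(), "HepG2", "NL2",
                              analysis_config(tumor_call_mode = "absolute"))
  expect_equal(calls$direction[calls$probe_id == "p2"], "hyper")  # 0.6 > 0.5 >= 0.1
  expect_equal(calls$direction[calls$probe_id == "p3"], "hypo")
})

test_that("gene hypermethylation needs a 5'-region hyper probe in that line", {
  map <- data.frame(probe_id = c("p1", "p3"), gene = "G",
                    region_group = c("BODY", "TSS200"), transcript_tag = NA,
                    chromosome = "1", position = 1:2, gene_order = 1:2)
  class(map) <- c("probe_gene_map", "data.frame")
  calls <- rbind(
    data.frame(probe_id = "p1", cell_line = "HepG2", beta_cell = 0.9,
               beta_ref = 0.1, delta_beta = 0.8, direction = "hyper"),
    data.frame(probe_id = "p3", cell_line = "HuH7", beta_cell = 0.9,
               beta_ref = 0.1, delta_beta = 0.8, direction = "hyper"))
  hs <- gene_hypermethylation(calls, map, "G")
  expect_false(hs$hypermethylated[hs$cell_line == "HepG2"])  # body-only
  expect_true(hs$hypermethylated[hs$cell_line == "HuH7"])    # TSS200
})

test_that("demethylation response takes the best condition with strict cutoff", {
  ctrl <- expression_matrix(matrix(10, 1, 1, dimnames = list("G", "HepG2")))
  t1 <- expression_matrix(matrix(15, 1, 1, dimnames = list("G", "HepG2")))
  t2 <- expression_matrix(matrix(25, 1, 1, dimnames = list("G", "HepG2")))
  r <- dac_response(ctrl, list(DAC_low = t1, DAC_high = t2), "G", "HepG2")
  expect_equal(r$fold_change, 2.5)
  expect_true(r$responsive)
  expect_equal(r$best_condition, "DAC_high")
  # boundary: exactly twofold is NOT responsive
  r2 <- dac_response(ctrl, list(DAC = expression_matrix(
    matrix(20, 1, 1, dimnames = list("G", "HepG2")))), "G", "HepG2")
  expect_equal(r2$fold_change, 2.0)
  expect_false(r2$responsive)
  # identity
  r3 <- dac_response(ctrl, list(DAC = ctrl), "G", "HepG2")
  expect_equal(r3$fold_change, 1.0)
  expect_false(r3$responsive)
  # zero control flagged undefined
  ctrl0 <- expression_matrix(matrix(0, 1, 1, dimnames = list("G", "HepG2")))
  expect_false(dac_response(ctrl0, list(DAC = t1), "G", "HepG2")$defined)
  # TSA-only condition is excluded by default but kept when configured
  r4 <- dac_response(ctrl, list(TSA = t2, DAC = t1), "G", "HepG2")
  expect_equal(r4$fold_change, 1.5)
  r5 <- dac_response(ctrl, list(TSA = t2, DAC = t1), "G", "HepG2",
                     analysis_config(include_tsa = TRUE))
  expect_equal(r5$fold_change, 2.5)
})

test_that("integration requires hyper and response in the same cell line", {
  hyper <- rbind(
    data.frame(gene = "G1", cell_line = "HuH7", hypermethylated = TRUE),
    data.frame(gene = "G1", cell_line = "HepG2", hypermethylated = FALSE),
    data.frame(gene = "G2", cell_line = "JHH1", hypermethylated = TRUE))
  dac <- rbind(
    data.frame(gene = "G1", cell_line = "HuH7", responsive = FALSE),
    data.frame(gene = "G1", cell_line = "HepG2", responsive = TRUE),
    data.frame(gene = "G2", cell_line = "JHH1", responsive = TRUE))
  reg <- integrate_regulated_genes(hyper, dac)
  expect_equal(reg$gene, "G2")                 # G1 evidence is cross-line
  expect_equal(reg$supporting_lines, "JHH1")
})

test_that("regulated-gene calls are non-increasing in both cutoffs", {
  co <- generate_cohort(default_sim(3))
  map <- build_probe_gene_map(co$manifest, co$panel)
  lines <- samples_in_group(co$beta, "hepatoma_line")
  n_reg <- function(db, fc) {
    cfg <- analysis_config(delta_beta_cutoff = db, fold_change_cutoff = fc)
    calls <- do.call(rbind, lapply(lines, function(cl)
      differential_calls(co$beta, cl, "NL2", cfg)))
    hyper <- do.call(rbind, lapply(co$panel$panel_genes$gene, function(g)
      gene_hypermethylation(calls, map, g)))
    dac <- do.call(rbind, lapply(co$panel$panel_genes$gene, function(g)
      do.call(rbind, lapply(lines, function(cl)
        dac_response(co$expr_dac_control, co$expr_dac_treated, g, cl, cfg)))))
    nrow(integrate_regulated_genes(hyper, dac, co$panel))
  }
  by_db <- vapply(c(0.2, 0.5, 0.75), n_reg, numeric(1), fc = 2)
  by_fc <- vapply(c(1.5, 2, 3, 5), n_reg, numeric(1), db = 0.5)
  expect_true(all(diff(by_db) <= 0))
  expect_true(all(diff(by_fc) <= 0))
  expect_equal(n_reg(0.5, 2), nrow(unique(co$truth$responsive["gene"])))
})
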