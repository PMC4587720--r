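test_that("75th-percentile normalization uses the type-7 quantile per sample", {
  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("G", 1:4), "S1"))
  e <- normalize_percentile75(expression_matrix(m))
  expect_equal(unname(stats::quantile(c(1, 2, 3, 4), 0.75, type = 7)), 3.25)
  expect_equal(e$values[, 1], c(1, 2, 3, 4) / 3.25, ignore_attr = TRUE)
  expect_equal(e$normalization_state, "percentile75")
  # idempotence
  e2 <- normalize_percentile75(e)
  expect_equal(e2$values, e$values)
  # all-equal column maps to 1
  mc <- matrix(7, 3, 1, dimnames = list(paste0("G", 1:3), "S1"))
  expect_true(all(normalize_percentile75(expression_matrix(mc))$values == 1))
  mz <- matrix(0, 3, 1, dimnames = list(paste0("G", 1:3), "S1"))
  expect_error(normalize_percentile75(expression_matrix(mz)), "S1")
})

test_that("reference-gene normalization yields percent-of-reference", {
  m <- matrix(c(2, 8, 4, 16), 2, 2,
              dimnames = list(c("G1", "ACTB"), c("S1", "S2")))
  e <- relative_to_reference(expression_matrix(m), "ACTB")
  expect_equal(e$values["G1", ], c(S1 = 25, S2 = 25))
  expect_true(all(e$values["ACTB", ] == 100))
  # proportional columns give identical relative profiles
  expect_equal(e$values[, "S1"], e$values[, "S2"])
  m["ACTB", "S2"] <- 0
  expect_error(relative_to_reference(expression_matrix(m), "ACTB"), "S2")
})

test_that("expression CV is the sample CV in percent and scale invariant", {
  m <- matrix(c(90, 100, 110), 1, 3,
              dimnames = list("G1", paste0("S", 1:3)))
  cv <- expression_cv(expression_matrix(m), "G1")
  expect_equal(cv$sd, 10)
  expect_equal(cv$cv_percent, 10.0)
  mc <- matrix(5, 1, 3, dimnames = dimnames(m))
  expect_equal(expression_cv(expression_matrix(mc), "G1")$cv_percent, 0)
  mz <- matrix(0, 1, 3, dimnames = dimnames(m))
  expect_false(expression_cv(expression_matrix(mz), "G1")$defined)
  set.seed(3)
  for (rep in 1:10) {
    v <- runif(8, 1, 100); c0 <- runif(1, 0.1, 50)
    m1 <- matrix(v, 1, 8, dimnames = list("G", paste0("S", 1:8)))
    m2 <- matrix(c0 * v, 1, 8, dimnames = list("G", paste0("S", 1:8)))
    expect_equal(expression_cv(expression_matrix(m1), "G")$cv_percent,
                 expression_cv(expression_matrix(m2), "G")$cv_percent)
  }
  ctrl <- do.call(rbind, list(
    expression_cv(expression_matrix(m), "G1"),
    expression_cv(expression_matrix(mc), "G1")))
  expect_equal(derive_cv_threshold(ctrl), 10.0)
})

test_that("multi-row genes are represented by the highest-mean row", {
  m <- matrix(c(1, 10, 2, 20), 2, 2,
              dimnames = list(c("G1", "G1"), c("S1", "S2")))
  v <- gene_expression_values(expression_matrix(m), "G1")
  expect_equal(unname(v), c(10, 20))
})

test_that("Spearman rho and p reproduce hand-derived and oracle values", {
  sp <- spearman_rho_p(c(1, 2, 3), c(3, 1, 2))
  expect_equal(sp$rho, -0.5)                   # 1 - 6*6/(3*8)
  sp2 <- spearman_rho_p(1:8, 8:1)
  expect_equal(sp2$rho, -1)
  expect_true(sp2$p_floored)
  expect_equal(sp2$p_value, .Machine$double.xmin)
  expect_true(spearman_rho_p(rep(1, 6), runif(6))$degenerate)
  # oracle equivalence to 1e-12, with and without ties
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(5:25, 1)
    x <- if (rep %% 2) runif(n) else sample(1:5, n, replace = TRUE)
    y <- if (rep %% 3) runif(n) else sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    o <- oracle_spearman(x, y)
    if (abs(o$rho) >= 1 - 1e-12) next
    sp <- spearman_rho_p(x, y)
    expect_equal(sp$rho, o$rho, tolerance = 1e-12)
    expect_equal(sp$p_value, o$p, tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(5)
  for (rep in 1:20) {
    x <- runif(12); y <- runif(12)
    r0 <- spearman_rho_p(x, y)$rho
    expect_equal(spearman_rho_p(exp(3 * x), y)$rho, r0)
    expect_equal(spearman_rho_p(x, rank(y)^3 + 1)$rho, r0)
  }
})

test_that("per-gene correlation flags constructed inverse relations", {
  map <- data.frame(probe_id = c("p1", "p2"), gene = "G",
                    region_group = c("TSS200", "BODY"), transcript_tag = NA,
                    chromosome = "1", position = c(1L, 2L), gene_order = 1:2)
  class(map) <- c("probe_gene_map", "data.frame")
  set.seed(1)
  b <- runif(10, 0.1, 0.9)
  bm <- beta_matrix(rbind(p1 = b, p2 = rep(0.5, 10)) |>
                      (\(m) {colnames(m) <- paste0("S", 1:10); m})())
  em <- expression_matrix(matrix(1 - b, 1, 10,
                                 dimnames = list("G", paste0("S", 1:10))),
                          normalization_state = "percentile75")
  res <- correlate_gene("G", bm, em, map)
  expect_equal(res$rho[res$probe_id == "p1"], -1)
  expect_true(res$inverse_significant[res$probe_id == "p1"])
  expect_true(attr(res, "gene_inverse_correlated"))
  # constant probe p2 is degenerate, not significant
  expect_false(any(res$inverse_significant[res$probe_id == "p2"]))

  em2 <- expression_matrix(matrix(1 - b, 1, 10,
                                  dimnames = list("G", paste0("X", 1:10))),
                           normalization_state = "percentile75")
  expect_error(correlate_gene("G", bm, em2, map), "no matched samples")
})
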