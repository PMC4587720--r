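# Independent oracles and tiny fixture builders used across the suite.

# brute-force Spearman: explicit average ranks + textbook Pearson formula,
# p from the t approximation written out independently of the package
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2))
}

# exact one-sample signed-rank p by explicit enumeration of all 2^n sign
# assignments (feasible for n <= 14)
oracle_wilcoxon <- function(cohort, reference) {
  d <- cohort - reference
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  allW <- as.vector(signs %*% r)
  p_le <- mean(allW <= W + 1e-12)
  p_ge <- mean(allW >= W - 1e-12)
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# minimal manifest CSV on disk
write_tiny_manifest <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "IlmnID,UCSC_RefGene_Name,UCSC_RefGene_Group,UCSC_RefGene_Accession,CHR,MAPINFO",
    "cg0001,GSTA4;GSTA4,TSS200;1stExon,NM_1;NM_1,6,100",
    "cg0002,GSTA4,5'UTR,NM_1,6,50",
    "cg0003,GSTA4,Body,NM_1,6,200",
    "cg0004,GSTT1;NEIGHBOR1,TSS1500;TSS200,NM_2;NM_3,22,500",
    "cg0005,,,,9,900",
    "cg0006,MINUSG,TSS200,NM_4,1,1000",
    "cg0007,MINUSG,Body,NM_4,1,800"
  ), path)
  path
}

tiny_panel <- function() {
  gene_panel(
    data.frame(gene = c("GSTA4", "GSTT1", "NEIGHBOR1", "MINUSG", "GHOST"),
               family = c("GST", "GST", "other", "other", "other"),
               stringsAsFactors = FALSE),
    control_methylation_genes = c("ACTB", "BMP4"),
    control_expression_genes = c("ACTB",  "B2M"),
    strand = c(MINUSG = "-"))
}

# beta matrix built directly from a named value list
make_beta <- function(values, groups = NULL) {
  beta_matrix(values, sample_groups = groups)
}

default_sim <- function(seed) simulation_config(seed = seed)
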