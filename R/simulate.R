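#' Simulation configuration for synthetic 450K-style cohorts
#'
#' Defines the study conditions the generator emulates: a normal-liver
#' cohort, a matched expression subset, hepatoma lines with planted promoter
#' hypermethylation and demethylation responses, genes with planted wide
#' inter-individual methylation ranges coupled to expression, and
#' housekeeping-pattern genes. Beta values are drawn from beta distributions
#' whose bounds hold by construction (no clipping).
#'
#' @param n_hvm,n_tsg,n_hkg,n_background Planted gene counts per class.
#' @param n_normal_samples Normal cohort size (default 20).
#' @param n_expression_samples Normals with matched expression (default 10).
#' @param n_tumor_lines Hepatoma cell lines (default 3).
#' @param probes_per_gene Named integer vector over region groups.
#' @param beta_baseline_5prime,beta_baseline_body Beta-distribution shape
#'   pairs for probe-level mean methylation in 5' and body regions.
#' @param hvm_range_effect Planted across-sample beta range at the HVM CpG.
#' @param control_range_anchor Largest inter-individual spread planted in a
#'   control gene; it becomes the variability threshold the pipeline derives.
#' @param stable_range_max Upper bound of the baseline inter-individual
#'   spread of non-planted probes (drawn uniformly from 0 to this value).
#' @param tumor_delta Planted tumor-minus-normal beta difference.
#' @param dac_fold Planted demethylation-treatment fold change.
#' @param coupling_strength Log-scale slope of expression on beta at the
#'   planted inverse-correlated CpG.
#' @param noise_sd Log-scale expression noise standard deviation.
#' @param concentration Beta-distribution concentration of per-sample draws
#'   around a probe's mean (larger = tighter technical spread).
#' @param seed Integer master seed; child seeds are derived per gene so one
#'   gene's draws do not perturb another's.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_hvm = 5L, n_tsg = 5L, n_hkg = 5L,
                              n_background = 15L,
                              n_normal_samples = 20L,
                              n_expression_samples = 10L,
                              n_tumor_lines = 3L,
                              probes_per_gene = c(TSS1500 = 2L, TSS200 = 2L,
                                                  FIVE_UTR = 1L, FIRST_EXON = 1L,
                                                  BODY = 3L, THREE_UTR = 1L),
                              beta_baseline_5prime = c(2, 18),
                              beta_baseline_body = c(9, 3),
                              hvm_range_effect = 0.6,
                              control_range_anchor = 0.25,
                              stable_range_max = 0.15,
                              tumor_delta = 0.7,
                              dac_fold = 4,
                              coupling_strength = 5,
                              noise_sd = 0.1,
                              concentration = 500,
                              seed = 1L) {
  if (!(hvm_range_effect > 0 && hvm_range_effect <= 0.8))
    stop("hvm_range_effect must be in (0, 0.8]: the planted CpG anchors at ",
         "beta 0.15 and must stay within [0,1] by construction")
  if (!(control_range_anchor > stable_range_max &&
        control_range_anchor < hvm_range_effect))
    stop("control_range_anchor must lie strictly between stable_range_max ",
         "and hvm_range_effect for the planted classes to be separable")
  if (!(tumor_delta > 0 && tumor_delta <= 0.8))
    stop("tumor_delta must be in (0, 0.8]")
  if (dac_fold <= 0) stop("dac_fold must be positive")
  if (concentration <= 2) stop("concentration must exceed 2")
  stopifnot(n_expression_samples <= n_normal_samples,
            all(probes_per_gene >= 0),
            all(names(probes_per_gene) %in% region_groups()))
  structure(as.list(environment()), class = "simulation_config")
}

# deterministic child seed per (master seed, unit index); keeps all seeds
# below 2^31 so set.seed() accepts them
child_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}

# per-sample beta draws around a probe mean mu with given concentration
rbeta_around <- function(n, mu, concentration) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  stats::rbeta(n, mu * concentration, (1 - mu) * concentration)
}

.sim_region_sequence <- function(probes_per_gene) {
  regs <- intersect(region_groups(), names(probes_per_gene))
  rep(regs, times = probes_per_gene[regs])
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces a manifest, a beta matrix over the normal cohort, a normal
#' reference, and hepatoma lines, raw expression matrices for the matched
#' normals and for control/treated cell lines, a \code{gene_panel}, and the
#' planted truth table. Planted classes:
#' \itemize{
#'   \item hvm — one TSS200 CpG whose per-sample means span
#'     \code{hvm_range_effect}, with expression a decreasing function of
#'     that CpG's beta (log-linear, slope \code{-coupling_strength}).
#'   \item tsg — stable low 5' methylation in normals; in one cell line the
#'     first TSS200 CpG gains \code{tumor_delta} and the gene responds to
#'     demethylating treatment with \code{dac_fold}.
#'   \item hkg — flat low 5' beta, high body beta, near-constant expression
#'     (CV below the housekeeping controls).
#'   \item background — baseline methylation, variable uncoupled expression.
#' }
#'
#' @param config A \code{simulation_config}.
#' @return List: manifest (probe_annotation), beta (beta_matrix over normals
#'   + reference "NL2" + tumor lines), expr (raw expression_matrix, matched
#'   normals), expr_dac_control / expr_dac_treated (cell-line expression,
#'   treated is a named list of conditions), panel, truth, config.
#' @export
generate_cohort <- function(config = simulation_config()) {
  genes <- c(
    if (config$n_hvm) paste0("HVMG", seq_len(config$n_hvm)),
    if (config$n_tsg) paste0("TSGG", seq_len(config$n_tsg)),
    if (config$n_hkg) paste0("HKGG", seq_len(config$n_hkg)),
    if (config$n_background) paste0("BGG", seq_len(config$n_background))
  )
  classes <- c(rep("hvm", config$n_hvm), rep("tsg", config$n_tsg),
               rep("hkg", config$n_hkg), rep("background", config$n_background))
  names(classes) <- genes
  controls_meth <- c("ACTB", "B2M", "GAPDH", "TBP", "BMP4", "IGFBP3", "MLH1", "MGMT")
  controls_expr <- c("ACTB", "B2M", "GAPDH", "TBP")
  families <- rep(c("CYP", "GST", "NAT", "SULT", "UGT"), length.out = length(genes))
  all_genes <- c(genes, controls_meth)
  strand <- stats::setNames(rep(c("+", "+", "+", "-"),
                                length.out = length(all_genes)), all_genes)
  panel <- gene_panel(data.frame(gene = genes, family = families,
                                 stringsAsFactors = FALSE),
                      control_methylation_genes = controls_meth,
                      control_expression_genes = controls_expr,
                      strand = strand)

  normals <- sprintf("L%02d", seq_len(config$n_normal_samples))
  lines <- paste0("T", seq_len(config$n_tumor_lines))
  samples <- c(normals, "NL2", lines)
  groups <- stats::setNames(c(rep("adult_liver", length(normals)),
                              "reference_normal",
                              rep("hepatoma_line", length(lines))), samples)
  region_seq <- .sim_region_sequence(config$probes_per_gene)
  p_per_gene <- length(region_seq)

  manifest_rows <- list()
  beta_rows <- list()
  truth_hvm <- truth_tsg <- truth_inverse <- list()
  hvm_argmax_beta <- list()  # per hvm gene: normal-cohort betas at planted CpG

  # per-sample probe means around a center with an inter-individual spread;
  # the spread shrinks near the boundaries (never the center shifts), so the
  # marginal mean of a probe equals its baseline draw exactly
  spread_means <- function(center, spread, n) {
    spread <- max(0, min(spread, 2 * (center - 0.02), 2 * (0.98 - center)))
    stats::runif(n, center - spread / 2, center + spread / 2)
  }
  # evenly spaced means spanning exactly `spread`, randomly assigned to
  # samples: the across-cohort range of a planted probe equals its effect
  spread_grid <- function(lo, spread, n) sample(lo + spread * (seq_len(n) - 1) / (n - 1))

  for (gi in seq_along(all_genes)) {
    g <- all_genes[gi]
    cls <- if (g %in% genes) classes[[g]] else "control"
    set.seed(child_seed(config$seed, gi))
    base_pos <- gi * 100000L
    offs <- seq_len(p_per_gene) * 137L
    pos <- if (identical(strand[[g]], "-")) base_pos + rev(offs) else base_pos + offs
    pids <- sprintf("cg%03d%03d", gi, seq_len(p_per_gene))
    is5 <- region_seq %in% c("TSS1500", "TSS200", "FIVE_UTR", "FIRST_EXON")
    mu <- numeric(p_per_gene)
    if (cls == "hkg") {
      # rigid housekeeping landscape: flat low 5', high body, no
      # inter-individual spread beyond technical noise
      mu[is5] <- stats::runif(sum(is5), 0.05, 0.15)
      mu[!is5] <- stats::runif(sum(!is5), 0.80, 0.90)
      spreads <- rep(0, p_per_gene)
    } else {
      mu[is5] <- stats::rbeta(sum(is5), config$beta_baseline_5prime[1],
                              config$beta_baseline_5prime[2])
      mu[!is5] <- stats::rbeta(sum(!is5), config$beta_baseline_body[1],
                               config$beta_baseline_body[2])
      spreads <- stats::runif(p_per_gene, 0, config$stable_range_max)
    }
    vals <- matrix(NA_real_, p_per_gene, length(samples),
                   dimnames = list(pids, samples))
    for (p in seq_len(p_per_gene)) {
      mu_s <- spread_means(mu[p], spreads[p], length(samples))
      vals[p, ] <- rbeta_around(length(samples), mu_s, config$concentration)
    }

    j <- which(region_seq == "TSS200")[1]
    if (cls == "hvm") {
      # planted wide-range CpG: across the normal cohort its means span the
      # configured effect exactly; tumor samples sit at the center
      vals[j, normals] <- rbeta_around(
        length(normals),
        spread_grid(0.15, config$hvm_range_effect, length(normals)),
        config$concentration * 4)
      vals[j, c("NL2", lines)] <- rbeta_around(
        length(lines) + 1, 0.15 + config$hvm_range_effect / 2,
        config$concentration * 4)
      truth_hvm[[g]] <- data.frame(gene = g, probe_id = pids[j],
                                   stringsAsFactors = FALSE)
      truth_inverse[[g]] <- data.frame(gene = g, probe_id = pids[j],
                                       stringsAsFactors = FALSE)
      hvm_argmax_beta[[g]] <- vals[j, normals]
    }
    if (cls == "tsg") {
      # stable low promoter in every normal; one line gains tumor_delta
      tsg_idx <- match(g, genes[classes == "tsg"])
      line <- lines[((tsg_idx - 1) %% length(lines)) + 1]
      mu_b <- stats::runif(1, 0.05, 0.2)
      vals[j, ] <- rbeta_around(length(samples), mu_b, config$concentration * 4)
      vals[j, line] <- rbeta_around(1, mu_b + config$tumor_delta,
                                    config$concentration * 4)
      truth_tsg[[g]] <- data.frame(gene = g, cell_line = line,
                                   probe_id = pids[j], stringsAsFactors = FALSE)
    }
    if (cls == "control") {
      # controls carry the largest uninteresting inter-individual spread;
      # the last control is the anchor whose range becomes the derived
      # variability threshold
      spread_c <- if (g == controls_meth[length(controls_meth)])
        config$control_range_anchor
      else stats::runif(1, 0.05, config$control_range_anchor * 0.8)
      vals[j, normals] <- rbeta_around(
        length(normals), spread_grid(0.15, spread_c, length(normals)),
        config$concentration * 4)
    }
    manifest_rows[[g]] <- data.frame(
      IlmnID = pids, UCSC_RefGene_Name = g,
      UCSC_RefGene_Group = c(TSS1500 = "TSS1500", TSS200 = "TSS200",
                             FIVE_UTR = "5'UTR", FIRST_EXON = "1stExon",
                             BODY = "Body", THREE_UTR = "3'UTR")[region_seq],
      UCSC_RefGene_Accession = paste0("NM_", gi),
      CHR = as.character((gi %% 22) + 1), MAPINFO = pos,
      stringsAsFactors = FALSE)
    beta_rows[[g]] <- vals
  }

  manifest_df <- do.call(rbind, manifest_rows)
  rownames(manifest_df) <- NULL
  manifest <- data.frame(manifest_df, stringsAsFactors = FALSE)
  class(manifest) <- c("probe_annotation", "data.frame")
  names(manifest)[names(manifest) == "UCSC_RefGene_Group"] <- "UCSC_RefGene_Group"
  # annotation rows in exploded form
  manifest$region_group <- map_region_token(manifest$UCSC_RefGene_Group)
  annotations <- data.frame(probe_id = manifest$IlmnID,
                            gene = manifest$UCSC_RefGene_Name,
                            region_group = manifest$region_group,
                            transcript_tag = manifest$UCSC_RefGene_Accession,
                            chromosome = manifest$CHR,
                            position = manifest$MAPINFO,
                            stringsAsFactors = FALSE)
  class(annotations) <- c("probe_annotation", "data.frame")

  beta <- beta_matrix(do.call(rbind, beta_rows), sample_groups = groups)

  # expression over the matched normal subset -----------------------------
  # Raw intensities carry a per-sample scale factor (array brightness) that
  # 75th-percentile normalization removes. A dense block of stable filler
  # transcripts stands in for the rest of the transcriptome so each column's
  # 75th percentile is estimated from many stable genes, as on a real array.
  expr_samples <- normals[seq_len(config$n_expression_samples)]
  n_filler <- 600L
  filler_profile <- exp(seq(log(5), log(500), length.out = n_filler))
  expr_genes <- c(genes, controls_expr, sprintf("FILLER%03d", seq_len(n_filler)))
  em <- matrix(NA_real_, length(expr_genes), length(expr_samples),
               dimnames = list(expr_genes, expr_samples))
  ctrl_base <- stats::setNames(c(1000, 500, 400, 300), controls_expr)
  for (gi in seq_along(c(genes, controls_expr))) {
    g <- expr_genes[gi]
    set.seed(child_seed(config$seed, 10000 + gi))
    cls <- if (g %in% genes) classes[[g]] else "hk_control"
    em[g, ] <- switch(cls,
      hvm = {
        b <- hvm_argmax_beta[[g]][expr_samples]
        100 * exp(config$coupling_strength * (0.5 - b) +
                    stats::rnorm(length(b), 0, config$noise_sd))
      },
      hkg = 200 * exp(stats::rnorm(length(expr_samples), 0, 0.005)),
      hk_control = ctrl_base[[g]] *
        exp(stats::rnorm(length(expr_samples), 0, 0.02)),
      # tsg and background: variable expression, uncoupled to methylation
      50 * exp(stats::rnorm(length(expr_samples), 0, 0.5)))
  }
  em[sprintf("FILLER%03d", seq_len(n_filler)), ] <- filler_profile
  set.seed(child_seed(config$seed, 9999))
  scale_i <- exp(stats::rnorm(length(expr_samples), 0, 0.15))
  em <- sweep(em, 2, scale_i, "*")
  expr <- expression_matrix(em, normalization_state = "raw")

  # cell-line expression: control and treated conditions ------------------
  dac_genes <- genes
  ctrl_m <- matrix(NA_real_, length(dac_genes), length(lines),
                   dimnames = list(dac_genes, lines))
  trt_m <- ctrl_m
  truth_resp <- list()
  for (gi in seq_along(dac_genes)) {
    g <- dac_genes[gi]
    set.seed(child_seed(config$seed, 20000 + gi))
    base <- 100 * exp(stats::rnorm(length(lines), 0, 0.2))
    fold <- exp(stats::rnorm(length(lines), 0, 0.05))
    if (classes[[g]] == "tsg") {
      line <- truth_tsg[[g]]$cell_line
      base[match(line, lines)] <- base[match(line, lines)] * 0.1  # silenced
      fold[match(line, lines)] <- config$dac_fold *
        exp(stats::rnorm(1, 0, 0.05))
      truth_resp[[g]] <- data.frame(gene = g, cell_line = line,
                                    stringsAsFactors = FALSE)
    }
    ctrl_m[g, ] <- base
    trt_m[g, ] <- base * fold
  }

  truth <- list(
    classes = classes,
    hvm_probes = if (length(truth_hvm)) do.call(rbind, truth_hvm) else NULL,
    tsg_events = if (length(truth_tsg)) do.call(rbind, truth_tsg) else NULL,
    responsive = if (length(truth_resp)) do.call(rbind, truth_resp) else NULL,
    inverse_probes = if (length(truth_inverse)) do.call(rbind, truth_inverse) else NULL
  )
  for (nm in c("hvm_probes", "tsg_events", "responsive", "inverse_probes"))
    if (!is.null(truth[[nm]])) rownames(truth[[nm]]) <- NULL

  list(manifest = annotations, beta = beta, expr = expr,
       expr_dac_control = expression_matrix(ctrl_m, "raw"),
       expr_dac_treated = list(DAC = expression_matrix(trt_m, "raw")),
       panel = panel, truth = truth, config = config)
}

#' Generate a synthetic shared-first-exon isoform locus
#'
#' Emulates a UGT1A-type locus: each isoform has a private first exon with
#' its own TSS-proximal CpGs. Hepatic-planted isoforms are unmethylated in
#' the liver cohort and methylated in the single intestine sample (and, less
#' strongly, in the fetal liver); intestinal-planted isoforms are mirrored.
#' Discordant-planted isoforms carry the methylation pattern opposite to
#' their tissue-dominant expression, so their first-exon methylation cannot
#' explain their expression.
#'
#' @param n_hepatic,n_intestinal Planted isoform counts (defaults 5 and 4).
#' @param n_discordant How many isoforms (taken from the end of the hepatic
#'   list) are planted discordant; default 1.
#' @param n_cohort Liver cohort size; default 18.
#' @param low_beta,high_beta Unmethylated / methylated first-exon levels.
#' @param concentration Beta-draw concentration (see
#'   \code{\link{simulation_config}}).
#' @param seed Integer seed.
#' @return List: map (probe_gene_map rows for the locus), beta
#'   (beta_matrix: cohort + "NSI" + "NLF"), isoforms (isoform,
#'   transcript_tag), tissue_expression (isoform, liver_mean,
#'   intestine_mean), truth (named logical: planted concordance).
#' @export
generate_isoform_locus <- function(n_hepatic = 5L, n_intestinal = 4L,
                                   n_discordant = 1L, n_cohort = 18L,
                                   low_beta = 0.1, high_beta = 0.8,
                                   concentration = 500, seed = 1L) {
  if (n_hepatic + n_intestinal < 2) stop("need at least two isoforms")
  if (n_discordant > n_hepatic) stop("n_discordant exceeds n_hepatic")
  iso <- c(paste0("ISO_H", seq_len(n_hepatic)),
           paste0("ISO_I", seq_len(n_intestinal)))
  cls <- c(rep("hepatic", n_hepatic), rep("intestinal", n_intestinal))
  discordant <- rep(FALSE, length(iso))
  if (n_discordant > 0)
    discordant[seq(n_hepatic - n_discordant + 1, n_hepatic)] <- TRUE
  tags <- paste0("NM_SYN", seq_along(iso))
  cohort <- sprintf("L%02d", seq_len(n_cohort))
  samples <- c(cohort, "NSI", "NLF")
  groups <- stats::setNames(c(rep("adult_liver", n_cohort),
                              "small_intestine", "fetal_liver"), samples)

  rows <- list(); beta_rows <- list(); expr_rows <- list()
  regions <- c("TSS1500", "TSS200", "FIRST_EXON")
  for (i in seq_along(iso)) {
    set.seed(child_seed(seed, 30000 + i))
    pids <- sprintf("cgIso%02d%d", i, seq_along(regions))
    pos <- i * 10000L + seq_along(regions) * 97L
    rows[[i]] <- data.frame(probe_id = pids, gene = "UGT1A_SYN",
                            region_group = regions, transcript_tag = tags[i],
                            chromosome = "2", position = pos,
                            gene_order = seq_along(regions),
                            stringsAsFactors = FALSE)
    # methylation pattern: hepatic = liver-low/NSI-high; intestinal mirrored;
    # discordant isoforms carry the opposite pattern for their class
    hepatic_pattern <- (cls[i] == "hepatic") != discordant[i]
    mu_liver <- if (hepatic_pattern) low_beta else high_beta
    mu_nsi <- if (hepatic_pattern) high_beta else low_beta
    mu_nlf <- if (hepatic_pattern) (low_beta + high_beta) / 2 else high_beta
    vals <- t(vapply(seq_along(regions), function(j) {
      c(rbeta_around(n_cohort, mu_liver, concentration),
        rbeta_around(1, mu_nsi, concentration),
        rbeta_around(1, mu_nlf, concentration))
    }, numeric(length(samples))))
    dimnames(vals) <- list(pids, samples)
    beta_rows[[i]] <- vals
    hi <- 100 * exp(stats::rnorm(1, 0, 0.1))
    lo <- 10 * exp(stats::rnorm(1, 0, 0.1))
    expr_rows[[i]] <- data.frame(
      isoform = iso[i],
      liver_mean = if (cls[i] == "hepatic") hi else lo,
      intestine_mean = if (cls[i] == "hepatic") lo else hi,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("probe_gene_map", "data.frame")
  list(map = map,
       beta = beta_matrix(do.call(rbind, beta_rows), sample_groups = groups),
       isoforms = data.frame(isoform = iso, transcript_tag = tags,
                             stringsAsFactors = FALSE),
       tissue_expression = do.call(rbind, expr_rows),
       truth = stats::setNames(!discordant, iso))
}

#' Write a generated cohort to disk in the package's file dialects
#'
#' @param cohort Output of \code{\link{generate_cohort}}.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    manifest = file.path(outdir, "manifest.csv"),
    beta = file.path(outdir, "beta.tsv"),
    expr = file.path(outdir, "expression.tsv"),
    dac_control = file.path(outdir, "expression_dac_control.tsv"),
    dac_treated = file.path(outdir, "expression_dac_treated_DAC.tsv"),
    groups = file.path(outdir, "sample_groups.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  ann <- cohort$manifest
  agg <- do.call(rbind, lapply(split(ann, ann$probe_id), function(d) {
    data.frame(IlmnID = d$probe_id[1],
               UCSC_RefGene_Name = paste(d$gene, collapse = ";"),
               UCSC_RefGene_Group = paste(
                 c(TSS1500 = "TSS1500", TSS200 = "TSS200", FIVE_UTR = "5'UTR",
                   FIRST_EXON = "1stExon", BODY = "Body",
                   THREE_UTR = "3'UTR")[d$region_group], collapse = ";"),
               UCSC_RefGene_Accession = paste(d$transcript_tag, collapse = ";"),
               CHR = d$chromosome[1], MAPINFO = d$position[1],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(agg, paths[["manifest"]], row.names = FALSE, quote = FALSE)
  write_matrix(cohort$beta, paths[["beta"]], id_column = "probe_id")
  write_matrix(cohort$expr, paths[["expr"]], id_column = "gene")
  write_matrix(cohort$expr_dac_control, paths[["dac_control"]], id_column = "gene")
  write_matrix(cohort$expr_dac_treated$DAC, paths[["dac_treated"]], id_column = "gene")
  write_table(data.frame(sample_id = names(cohort$beta$sample_groups),
                         group = unname(cohort$beta$sample_groups)),
              paths[["groups"]])
  jsonlite::write_json(list(classes = as.list(cohort$truth$classes)),
                       paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
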