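#' Construct a validated beta-value matrix
#'
#' @param values Numeric matrix, probes in rows, samples in columns; entries
#'   are beta values in [0,1] or NA (missing; never imputed).
#' @param sample_groups Optional named character vector sample_id -> group
#'   label (e.g. adult_liver, fetal_liver, small_intestine, hepatoma_line).
#' @return An object of class \code{beta_matrix}.
#' @export
beta_matrix <- function(values, sample_groups = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]))
  }
  if (!is.null(sample_groups)) {
    sample_groups <- sample_groups[colnames(values)]
    names(sample_groups) <- colnames(values)
  }
  structure(list(values = values, sample_groups = sample_groups),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  if (!is.null(x$sample_groups)) {
    tb <- table(x$sample_groups, useNA = "ifany")
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Samples of a beta matrix belonging to a group
#' @param beta A \code{beta_matrix}.
#' @param group Group label(s) to select; NULL returns all samples.
#' @return Character vector of sample IDs.
#' @export
samples_in_group <- function(beta, group = NULL) {
  if (is.null(group)) return(colnames(beta$values))
  if (is.null(beta$sample_groups)) stop("beta matrix carries no sample groups")
  names(beta$sample_groups)[beta$sample_groups %in% group]
}

#' Read a beta-value matrix from delimited text
#'
#' First column holds probe IDs, header row holds sample IDs. Empty cells
#' and NA tokens become missing values (kept missing, never zero). Values
#' outside [0,1] are a validation error naming the offending probe/sample.
#'
#' @param path File path (TSV or CSV; the delimiter is sniffed from the
#'   header line).
#' @param sample_group_map Optional named vector sample_id -> group label.
#' @return A \code{beta_matrix}.
#' @export
read_beta_matrix <- function(path, sample_group_map = NULL) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2) stop("malformed header: need a probe-ID column plus sample columns")
  probes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))
    nonnum <- is.na(m2) & !is.na(as.matrix(df[, -1, drop = FALSE])) &
      nzchar(trimws(as.matrix(df[, -1, drop = FALSE])))
    if (any(nonnum)) stop("non-numeric beta value in ", path)
    m <- m2
  }
  rownames(m) <- probes
  beta_matrix(m, sample_groups = sample_group_map)
}

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns; all
#'   values nonnegative.
#' @param normalization_state One of "raw", "percentile75",
#'   "reference_gene_percent".
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values,
                              normalization_state = c("raw", "percentile75",
                                                      "reference_gene_percent")) {
  normalization_state <- match.arg(normalization_state)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  structure(list(values = values, normalization_state = normalization_state),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples [", x$normalization_state, "]\n")
  invisible(x)
}

#' Read an expression matrix from delimited text
#' @param path File path (genes x samples, first column gene IDs).
#' @param normalization_state Normalization state of the stored values.
#' @return An \code{expression_matrix}.
#' @export
read_expression_matrix <- function(path, normalization_state = "raw") {
  df <- read_delim_auto(path)
  if (ncol(df) < 2) stop("malformed header: need a gene-ID column plus sample columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, normalization_state = normalization_state)
}

#' Read a 450K-dialect probe manifest
#'
#' Expects columns IlmnID, UCSC_RefGene_Name, UCSC_RefGene_Group, CHR,
#' MAPINFO. The gene-name and region-group fields are semicolon-delimited
#' parallel lists (one entry per transcript assignment) which are exploded
#' into per-(gene, region) rows. Manifest spellings of region groups are
#' mapped onto the canonical vocabulary; unknown tokens are errors. An
#' optional UCSC_RefGene_Accession column supplies transcript tags, also
#' semicolon-parallel.
#'
#' @param path CSV/TSV manifest path.
#' @return data.frame of class \code{probe_annotation} with one row per
#'   (probe, gene, region) assignment; unannotated probes are retained with
#'   NA gene.
#' @export
read_manifest <- function(path) {
  df <- read_delim_auto(path)
  need <- c("IlmnID", "UCSC_RefGene_Name", "UCSC_RefGene_Group", "CHR", "MAPINFO")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  has_acc <- "UCSC_RefGene_Accession" %in% names(df)
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pid <- as.character(df$IlmnID[i])
    pos <- as.integer(df$MAPINFO[i])
    if (!is.na(pos) && pos < 1) stop("position < 1 for probe ", pid)
    genes <- split_semicolon(df$UCSC_RefGene_Name[i])
    regs  <- split_semicolon(df$UCSC_RefGene_Group[i])
    accs  <- if (has_acc) split_semicolon(df$UCSC_RefGene_Accession[i]) else character(0)
    if (length(genes) == 0) {
      rows[[i]] <- data.frame(probe_id = pid, gene = NA_character_,
                              region_group = NA_character_,
                              transcript_tag = NA_character_,
                              chromosome = as.character(df$CHR[i]),
                              position = pos, stringsAsFactors = FALSE)
      next
    }
    if (length(genes) != length(regs))
      stop("gene/region lists of unequal length for probe ", pid)
    if (length(accs) && length(accs) != length(genes))
      stop("gene/accession lists of unequal length for probe ", pid)
    asg <- data.frame(probe_id = pid, gene = genes,
                      region_group = map_region_token(regs),
                      transcript_tag = if (length(accs)) accs else NA_character_,
                      chromosome = as.character(df$CHR[i]),
                      position = pos, stringsAsFactors = FALSE)
    # a (gene, region, transcript) pair is a single assignment per probe
    asg <- unique(asg)
    rows[[i]] <- asg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("probe_annotation", "data.frame")
  out
}

split_semicolon <- function(x) {
  if (is.na(x) || !nzchar(trimws(as.character(x)))) return(character(0))
  trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' Build the probe -> gene -> region map for a panel
#'
#' For every panel and control gene, collects its probe assignments and
#' orders them 5' to 3': ascending genomic position for plus-strand genes,
#' descending for minus-strand (strand is supplied by the panel; default
#' plus). A probe annotated to several genes appears under each. Panel genes
#' with no probes are flagged with a warning and listed in the
#' \code{no_probe_genes} attribute.
#'
#' @param annotations A \code{probe_annotation} data.frame from
#'   \code{\link{read_manifest}}.
#' @param panel A \code{gene_panel}.
#' @return data.frame of class \code{probe_gene_map} with columns probe_id,
#'   gene, region_group, transcript_tag, chromosome, position, gene_order
#'   (1 = 5'-most probe of the gene).
#' @export
build_probe_gene_map <- function(annotations, panel) {
  genes <- panel_all_genes(panel)
  ann <- annotations[!is.na(annotations$gene) & annotations$gene %in% genes, ,
                     drop = FALSE]
  pieces <- list()
  no_probes <- character(0)
  for (g in genes) {
    sub <- ann[ann$gene == g, , drop = FALSE]
    if (nrow(sub) == 0) {
      no_probes <- c(no_probes, g)
      next
    }
    decreasing <- identical(gene_strand(panel, g), "-")
    sub <- sub[order(sub$position, decreasing = decreasing), , drop = FALSE]
    ord <- match(sub$position, unique(sub$position))
    sub$gene_order <- ord
    pieces[[g]] <- sub
  }
  if (length(no_probes))
    warning("panel gene(s) with no probes in manifest: ",
            paste(no_probes, collapse = ", "))
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(probe_id = character(0), gene = character(0),
               region_group = character(0), transcript_tag = character(0),
               chromosome = character(0), position = integer(0),
               gene_order = integer(0))
  rownames(out) <- NULL
  attr(out, "no_probe_genes") <- no_probes
  class(out) <- c("probe_gene_map", "data.frame")
  out
}

#' Probes of one gene, 5' to 3'
#' @param map A \code{probe_gene_map}.
#' @param gene Gene symbol.
#' @param region_set Optional region-group filter.
#' @return The gene's rows of the map, in 5'->3' order.
#' @export
gene_probes <- function(map, gene, region_set = NULL) {
  sub <- map[map$gene == gene, , drop = FALSE]
  if (!is.null(region_set))
    sub <- sub[sub$region_group %in% region_set, , drop = FALSE]
  sub[order(sub$gene_order), , drop = FALSE]
}

#' Read a gene panel from YAML or JSON
#'
#' The file holds \code{panel_genes} (map family -> list of symbols, or list
#' of \code{\{gene, family\}} records), optional \code{control_methylation_genes},
#' \code{control_expression_genes}, \code{strand} (map gene -> "+"/"-") and
#' \code{isoform_loci} (map locus -> list of \code{\{isoform, transcript_tag\}}).
#'
#' @param path Panel file path (.yaml/.yml/.json).
#' @return A \code{gene_panel}.
#' @export
read_gene_panel <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  pg <- raw$panel_genes
  if (is.null(pg)) stop("panel file lacks 'panel_genes'")
  if (!is.null(names(pg)) && all(nzchar(names(pg)))) {
    panel_genes <- do.call(rbind, lapply(names(pg), function(fam) {
      data.frame(gene = unlist(pg[[fam]], use.names = FALSE), family = fam,
                 stringsAsFactors = FALSE)
    }))
  } else {
    panel_genes <- do.call(rbind, lapply(pg, function(r)
      data.frame(gene = r$gene, family = r$family, stringsAsFactors = FALSE)))
  }
  args <- list(panel_genes = panel_genes)
  if (!is.null(raw$control_methylation_genes))
    args$control_methylation_genes <- unlist(raw$control_methylation_genes)
  if (!is.null(raw$control_expression_genes))
    args$control_expression_genes <- unlist(raw$control_expression_genes)
  if (!is.null(raw$strand)) args$strand <- unlist(raw$strand)
  if (!is.null(raw$isoform_loci)) {
    args$isoform_loci <- lapply(raw$isoform_loci, function(lst)
      do.call(rbind, lapply(lst, function(r)
        data.frame(isoform = r$isoform, transcript_tag = r$transcript_tag,
                   stringsAsFactors = FALSE))))
  }
  do.call(gene_panel, args)
}

#' The packaged default DME gene panel
#'
#' 55 cytochrome P450 genes and 62 phase II conjugation genes (17 GST,
#' 10 NAT, 13 SULT, 22 UGT) with the eight standard methylation control
#' genes and four housekeeping expression controls.
#'
#' @return A \code{gene_panel}.
#' @export
default_dme_panel <- function() {
  read_gene_panel(system.file("extdata", "dme_panel.yaml", package = "methscape"))
}

#' Write a result table as TSV
#'
#' Delimited text with a header and the data.frame's column order; row names
#' are never written. Used for all stage outputs.
#'
#' @param result A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Write a matrix-shaped object (beta or expression) as TSV
#' @param x A \code{beta_matrix} or \code{expression_matrix}.
#' @param path Output path.
#' @param id_column Name for the first (row-ID) column.
#' @return The path, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "id") {
  m <- if (inherits(x, c("beta_matrix", "expression_matrix"))) x$values else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("malformed header in ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
                    na.strings = c("NA", ""))
}
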