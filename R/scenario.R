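#' Declare a small synthetic genome
#'
#' The evidence generator places genes, variants and CpG sites on a declared
#' genome so interval arithmetic (including clamping at chromosome ends) is
#' exercised at desk scale.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @return data.frame with columns `chrom`, `length`.
#' @export
synthetic_genome <- function(n_chrom = 2L, chrom_len = 1e7) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = as.integer(chrom_len),
             stringsAsFactors = FALSE)
}

#' Planted truth for a prioritization scenario
#'
#' Describes which genes carry a complete four-way evidence chain (causal) and
#' which are decoys missing exactly one link, so the cascade's output can be
#' checked against construction.
#'
#' @param causal_genes Character vector of gene ids with all evidence planted.
#' @param decoy_genes Named character vector: names are gene ids, values name
#'   the single withheld link, one of `"DMe"`, `"eQTM"`, `"eQTL"`, `"DExpr"`,
#'   `"GLI-signal"`.
#' @param variant_gene_assignments Named character vector: names are variant
#'   ids, values the gene each variant is anchored to. Every causal and decoy
#'   gene must receive at least one variant.
#' @return An object of class `scenario_truth`.
#' @examples
#' scenario_truth(c("g1"), c(g2 = "eQTM"), c(rs1 = "g1", rs2 = "g2"))
#' @export
scenario_truth <- function(causal_genes = character(0),
                           decoy_genes = character(0),
                           variant_gene_assignments = character(0)) {
  causal_genes <- as.character(causal_genes)
  links <- c("DMe", "eQTM", "eQTL", "DExpr", "GLI-signal")
  if (length(decoy_genes)) {
    if (is.null(names(decoy_genes)) || any(names(decoy_genes) == "")) {
      stop_gliprio("consistency_failure", "decoy_genes must be named by gene id")
    }
    bad <- setdiff(unique(decoy_genes), links)
    if (length(bad)) {
      stop_gliprio("consistency_failure", "unknown withheld link(s): ",
                   paste(bad, collapse = ", "))
    }
  }
  if (length(intersect(causal_genes, names(decoy_genes)))) {
    stop_gliprio("consistency_failure", "causal and decoy gene sets overlap")
  }
  genes <- c(causal_genes, names(decoy_genes))
  if (length(variant_gene_assignments)) {
    bad <- setdiff(unique(variant_gene_assignments), genes)
    if (length(bad)) {
      stop_gliprio("consistency_failure",
                   "variants assigned to unknown genes: ",
                   paste(bad, collapse = ", "))
    }
  }
  missing <- setdiff(genes, variant_gene_assignments)
  if (length(missing)) {
    stop_gliprio("consistency_failure", "genes with no assigned variant: ",
                 paste(missing, collapse = ", "))
  }
  structure(list(causal_genes = causal_genes,
                 decoy_genes = decoy_genes,
                 variant_gene_assignments = variant_gene_assignments),
            class = "scenario_truth")
}

# tissue labels used for synthetic eQTL links
.gliprio_tissues <- c("Whole Blood", "Lung", "Thyroid", "Artery Aorta",
                      "Liver", "Muscle Skeletal", "Nerve Tibial",
                      "Adipose Subcutaneous")

#' Generate evidence tables and gene annotation from planted truth
#'
#' Lays out every truth gene on the synthetic genome (an exon span of 2-4
#' exons), anchors its assigned variant(s) within 100 kb of the gene, places
#' one CpG within 200 kb of each variant, and emits the four evidence tables
#' (differential methylation, eQTM, eQTL, differential expression) with
#' explicit boolean significance flags. Causal genes receive all four
#' significant links; each decoy has exactly its withheld link rendered
#' non-significant (a `"GLI-signal"` decoy keeps all omics links — its variant
#' simply carries no interaction signal, see [scenario_selected_variants()]).
#'
#' @param truth A [scenario_truth()] object.
#' @param genome A [synthetic_genome()] data.frame.
#' @param seed Integer seed.
#' @param trait,exposure Context of the scenario's analysis set.
#' @return A list of class `evidence_tables` with elements `dme`, `eqtm`,
#'   `eqtl`, `dexpr`, `annotation` (exon-level gene annotation), and
#'   `variants` (variant id, chrom, pos, gene).
#' @export
generate_evidence_tables <- function(truth, genome = synthetic_genome(),
                                     seed = 1L, trait = "HDL",
                                     exposure = "current smoking") {
  stopifnot(inherits(truth, "scenario_truth"))
  set.seed(substream_seed(seed, "evidence"))
  genes <- c(truth$causal_genes, names(truth$decoy_genes))
  withheld <- c(stats::setNames(rep("", length(truth$causal_genes)),
                                truth$causal_genes),
                truth$decoy_genes)

  if (!length(genes)) {
    empty <- list(
      dme = data.frame(cpg_id = character(0), chrom = character(0),
                       pos = integer(0), context = character(0),
                       effect_direction = character(0), p = numeric(0),
                       significant = logical(0)),
      eqtm = data.frame(cpg_id = character(0), gene_id = character(0),
                        p = numeric(0), significant = logical(0)),
      eqtl = data.frame(variant_id = character(0), gene_id = character(0),
                        tissue = character(0), slope = numeric(0),
                        p = numeric(0), significant = logical(0)),
      dexpr = data.frame(gene_id = character(0), exposure = character(0),
                         direction = character(0), p = numeric(0),
                         significant = logical(0)),
      annotation = data.frame(chrom = character(0), exon_start = integer(0),
                              exon_end = integer(0), gene_id = character(0),
                              transcript_id = character(0)),
      variants = data.frame(variant_id = character(0), chrom = character(0),
                            pos = integer(0), gene_id = character(0))
    )
    return(structure(empty, class = c("evidence_tables", "list")))
  }

  sig_p <- function(k) 10^stats::runif(k, -10, -6)
  null_p <- function(k) stats::runif(k, 0.1, 0.9)

  # gene layout: exon span well inside a chromosome
  ann <- list(); gene_pos <- list()
  for (g in genes) {
    row <- genome[sample.int(nrow(genome), 1L), ]
    start <- as.integer(stats::runif(1, 8e5, row$length - 8e5))
    k_ex <- sample(2:4, 1L)
    ex_start <- sort(as.integer(start + stats::runif(k_ex, 0, 3e4)))
    ex_end <- as.integer(ex_start + stats::runif(k_ex, 200, 3000))
    ann[[g]] <- data.frame(chrom = row$chrom, exon_start = ex_start,
                           exon_end = ex_end, gene_id = g,
                           transcript_id = paste0(g, ".t1"),
                           stringsAsFactors = FALSE)
    gene_pos[[g]] <- list(chrom = row$chrom, start = start,
                          len = row$length)
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL

  # variants anchored near their gene
  vids <- names(truth$variant_gene_assignments)
  variants <- do.call(rbind, lapply(vids, function(v) {
    g <- truth$variant_gene_assignments[[v]]
    gp <- gene_pos[[g]]
    pos <- as.integer(min(max(gp$start + round(stats::runif(1, -1e5, 1e5)), 1),
                          gp$len))
    data.frame(variant_id = v, chrom = gp$chrom, pos = pos, gene_id = g,
               stringsAsFactors = FALSE)
  }))

  # one CpG per variant, within 200 kb
  cpg <- variants
  cpg$cpg_id <- paste0("cg", sprintf("%08d", seq_len(nrow(cpg))))
  cpg$cpg_pos <- as.integer(pmin(pmax(
    cpg$pos + round(stats::runif(nrow(cpg), -2e5, 2e5)), 1),
    vapply(cpg$gene_id, function(g) gene_pos[[g]]$len, numeric(1))))

  dme <- data.frame(
    cpg_id = cpg$cpg_id, chrom = cpg$chrom, pos = cpg$cpg_pos,
    context = exposure,
    effect_direction = sample(c("up", "down"), nrow(cpg), replace = TRUE),
    p = ifelse(withheld[cpg$gene_id] == "DMe", null_p(nrow(cpg)),
               sig_p(nrow(cpg))),
    significant = withheld[cpg$gene_id] != "DMe",
    stringsAsFactors = FALSE
  )
  rownames(dme) <- NULL

  eqtm <- data.frame(
    cpg_id = cpg$cpg_id, gene_id = cpg$gene_id,
    p = ifelse(withheld[cpg$gene_id] == "eQTM", null_p(nrow(cpg)),
               sig_p(nrow(cpg))),
    significant = withheld[cpg$gene_id] != "eQTM",
    stringsAsFactors = FALSE
  )
  rownames(eqtm) <- NULL

  eqtl <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    g <- variants$gene_id[i]
    tis <- sample(.gliprio_tissues, sample(1:2, 1L))
    sig <- withheld[[g]] != "eQTL"
    data.frame(variant_id = variants$variant_id[i], gene_id = g, tissue = tis,
               slope = stats::rnorm(length(tis), 0, 0.5),
               p = if (sig) sig_p(length(tis)) else null_p(length(tis)),
               significant = sig, stringsAsFactors = FALSE)
  }))
  rownames(eqtl) <- NULL

  dexpr <- data.frame(
    gene_id = genes,
    exposure = exposure_class(exposure),
    direction = sample(c("up", "down"), length(genes), replace = TRUE),
    p = ifelse(withheld[genes] == "DExpr", null_p(length(genes)),
               sig_p(length(genes))),
    significant = withheld[genes] != "DExpr",
    stringsAsFactors = FALSE
  )
  rownames(dexpr) <- NULL

  structure(list(dme = dme, eqtm = eqtm, eqtl = eqtl, dexpr = dexpr,
                 annotation = annotation,
                 variants = variants[, c("variant_id", "chrom", "pos",
                                         "gene_id")]),
            class = c("evidence_tables", "list"))
}

#' Selected-variant table implied by a scenario's truth
#'
#' Builds the screened GLI-variant table the evidence cascade consumes:
#' variants assigned to causal genes and to decoys whose withheld link is an
#' omics link appear with an interaction p below the screen; a variant whose
#' gene withholds the `"GLI-signal"` link never enters the selection.
#'
#' @param truth A [scenario_truth()] object.
#' @param evidence The matching [generate_evidence_tables()] output.
#' @param trait,exposure,ancestry_group Analysis-set context tags.
#' @param alpha Interaction-screen threshold used to place synthetic p-values.
#' @param seed Integer seed.
#' @return A selected-variant data.frame (variant_id, chrom, pos, trait,
#'   exposure, ancestry_group, p_int).
#' @export
scenario_selected_variants <- function(truth, evidence, trait = "HDL",
                                       exposure = "current smoking",
                                       ancestry_group = "AA",
                                       alpha = 5e-5, seed = 1L) {
  stopifnot(inherits(truth, "scenario_truth"))
  set.seed(substream_seed(seed, "selected"))
  v <- evidence$variants
  silent <- names(truth$decoy_genes)[truth$decoy_genes == "GLI-signal"]
  keep <- v[!(v$gene_id %in% silent), , drop = FALSE]
  if (!nrow(keep)) {
    return(data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), trait = character(0),
                      exposure = character(0), ancestry_group = character(0),
                      p_int = numeric(0)))
  }
  data.frame(variant_id = keep$variant_id, chrom = keep$chrom, pos = keep$pos,
             trait = trait, exposure = exposure,
             ancestry_group = ancestry_group,
             p_int = alpha * stats::runif(nrow(keep), 0.01, 0.9),
             stringsAsFactors = FALSE, row.names = NULL)
}
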