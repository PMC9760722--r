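#' Pair screened GLI variants with nearby differentially methylated sites
#'
#' For each selected variant, finds significant DMe sites on the same
#' chromosome within `flank` bp (inclusive distance) whose association context
#' matches the variant's analysis set. In the default `"or"` mode a site
#' qualifies if its context equals the variant's trait or its exposure; in
#' `"and"` mode the site must have significant records for both.
#'
#' @param selected Selected-variant data.frame (columns `variant_id`, `chrom`,
#'   `pos`, `trait`, `exposure`, `ancestry_group`).
#' @param dme DMe table: `cpg_id`, `chrom`, `pos`, `context`, `significant`.
#' @param flank Maximum variant-to-site distance in bp (inclusive); default
#'   500000.
#' @param context_mode `"or"` (default) or `"and"`.
#' @return data.frame of pairs: variant_id, chrom, variant_pos, trait,
#'   exposure, ancestry_group, cpg_id, cpg_pos, distance.
#' @export
find_dnam_near_variants <- function(selected, dme, flank = 500000L,
                                    context_mode = c("or", "and")) {
  context_mode <- match.arg(context_mode)
  empty <- data.frame(variant_id = character(0), chrom = character(0),
                      variant_pos = integer(0), trait = character(0),
                      exposure = character(0), ancestry_group = character(0),
                      cpg_id = character(0), cpg_pos = integer(0),
                      distance = integer(0))
  if (!nrow(selected) || !nrow(dme)) return(empty)
  sig <- dme[dme$significant, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  out <- lapply(seq_len(nrow(selected)), function(i) {
    v <- selected[i, ]
    near <- sig[sig$chrom == v$chrom &
                  abs(sig$pos - v$pos) <= flank, , drop = FALSE]
    if (!nrow(near)) return(NULL)
    if (context_mode == "or") {
      near <- near[near$context %in% c(v$trait, v$exposure), , drop = FALSE]
    } else {
      ctx <- split(near$context, near$cpg_id)
      ok <- names(ctx)[vapply(ctx, function(cc) {
        all(c(v$trait, v$exposure) %in% cc)
      }, logical(1))]
      near <- near[near$cpg_id %in% ok, , drop = FALSE]
    }
    if (!nrow(near)) return(NULL)
    near <- near[!duplicated(near$cpg_id), , drop = FALSE]
    data.frame(variant_id = v$variant_id, chrom = v$chrom,
               variant_pos = v$pos, trait = v$trait, exposure = v$exposure,
               ancestry_group = v$ancestry_group,
               cpg_id = near$cpg_id, cpg_pos = near$pos,
               distance = abs(near$pos - v$pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# deterministic ordering used for all locus tables
order_loci <- function(loci) {
  loci[order(loci$ancestry_group, loci$trait, loci$exposure,
             -loci$n_variants, loci$gene_id), , drop = FALSE]
}

#' Prioritize loci by joint eQTL and eQTM gene linkage
#'
#' A gene qualifies in a (variant, CpG) pair's context when the variant is a
#' significant eQTL for the gene in at least one tissue and the CpG is a
#' significant eQTM for the same gene. Qualifying evidence is aggregated per
#' (gene, ancestry_group, trait, exposure) with the supporting variant list,
#' CpG list and the union of eQTL tissues.
#'
#' @param pairs Output of [find_dnam_near_variants()].
#' @param eqtl eQTL table: `variant_id`, `gene_id`, `tissue`, `significant`.
#' @param eqtm eQTM table: `cpg_id`, `gene_id`, `significant`.
#' @return Locus data.frame at tier `"prioritized"` with columns
#'   ancestry_group, trait, exposure, gene_id, tier, n_variants, variant_ids,
#'   cpg_ids, eqtl_tissues.
#' @export
prioritize <- function(pairs, eqtl, eqtm) {
  empty <- data.frame(ancestry_group = character(0), trait = character(0),
                      exposure = character(0), gene_id = character(0),
                      tier = character(0), n_variants = integer(0),
                      variant_ids = character(0), cpg_ids = character(0),
                      eqtl_tissues = character(0))
  if (!nrow(pairs)) return(empty)
  eqtl_sig <- eqtl[eqtl$significant, , drop = FALSE]
  eqtm_sig <- eqtm[eqtm$significant, , drop = FALSE]
  if (!nrow(eqtl_sig) || !nrow(eqtm_sig)) return(empty)

  hits <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    g_eqtl <- unique(eqtl_sig$gene_id[eqtl_sig$variant_id == pr$variant_id])
    g_eqtm <- unique(eqtm_sig$gene_id[eqtm_sig$cpg_id == pr$cpg_id])
    genes <- intersect(g_eqtl, g_eqtm)
    if (!length(genes)) return(NULL)
    data.frame(gene_id = genes, ancestry_group = pr$ancestry_group,
               trait = pr$trait, exposure = pr$exposure,
               variant_id = pr$variant_id, cpg_id = pr$cpg_id,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)

  key <- interaction(hits$gene_id, hits$ancestry_group, hits$trait,
                     hits$exposure, drop = TRUE)
  loci <- do.call(rbind, lapply(split(hits, key), function(h) {
    vids <- sort(unique(h$variant_id))
    tiss <- sort(unique(eqtl_sig$tissue[
      eqtl_sig$variant_id %in% vids & eqtl_sig$gene_id == h$gene_id[1]]))
    data.frame(ancestry_group = h$ancestry_group[1], trait = h$trait[1],
               exposure = h$exposure[1], gene_id = h$gene_id[1],
               tier = "prioritized", n_variants = length(vids),
               variant_ids = paste(vids, collapse = ","),
               cpg_ids = paste(sort(unique(h$cpg_id)), collapse = ","),
               eqtl_tissues = paste(tiss, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  order_loci(loci)
}

#' Promote prioritized loci with matching differential expression
#'
#' A prioritized locus is further prioritized when its gene has a significant
#' differential-expression record for the locus exposure's class (current and
#' ever smoking both match smoking DExpr evidence; the drinking exposures
#' match alcohol DExpr evidence).
#'
#' @param prioritized Locus data.frame from [prioritize()].
#' @param dexpr DExpr table: `gene_id`, `exposure` (class label or full
#'   exposure label), `significant`.
#' @return The subset of loci, with tier set to `"further_prioritized"`.
#' @export
further_prioritize <- function(prioritized, dexpr) {
  if (!nrow(prioritized)) return(prioritized)
  dx <- dexpr[dexpr$significant, , drop = FALSE]
  if (nrow(dx)) {
    full <- dx$exposure %in% gli_exposures()
    dx$class <- dx$exposure
    dx$class[full] <- exposure_class(dx$exposure[full])
  }
  keep <- vapply(seq_len(nrow(prioritized)), function(i) {
    cls <- exposure_class(prioritized$exposure[i])
    nrow(dx) > 0 &&
      any(dx$gene_id == prioritized$gene_id[i] & dx$class == cls)
  }, logical(1))
  out <- prioritized[keep, , drop = FALSE]
  if (nrow(out)) out$tier <- "further_prioritized"
  rownames(out) <- NULL
  out
}

# candidate genes: selected variant inside the gene window, plus a qualifying
# DMe site. Convention "gene_window": the DMe site lies inside the gene
# window; convention "cpg_window": the DMe site lies within flank of the
# variant itself (the variant-CpG pairs).
candidate_loci <- function(selected, dme, windows, pairs, flank,
                           context_mode = "or",
                           dme_scope = c("gene_window", "cpg_window")) {
  dme_scope <- match.arg(dme_scope)
  empty <- data.frame(ancestry_group = character(0), trait = character(0),
                      exposure = character(0), gene_id = character(0),
                      tier = character(0), n_variants = integer(0),
                      variant_ids = character(0), cpg_ids = character(0),
                      eqtl_tissues = character(0))
  if (!nrow(selected) || !nrow(windows)) return(empty)
  idx <- build_interval_index(windows)
  sig <- dme[dme$significant, , drop = FALSE]
  rows <- lapply(seq_len(nrow(selected)), function(i) {
    v <- selected[i, ]
    w <- query_interval_index(idx, v$chrom, v$pos)
    if (!nrow(w)) return(NULL)
    out <- lapply(seq_len(nrow(w)), function(j) {
      if (dme_scope == "gene_window") {
        s <- sig[sig$chrom == w$chrom[j] &
                   sig$pos >= w$window_start[j] &
                   sig$pos <= w$window_end[j], , drop = FALSE]
        if (context_mode == "or") {
          s <- s[s$context %in% c(v$trait, v$exposure), , drop = FALSE]
        } else {
          ctx <- split(s$context, s$cpg_id)
          ok <- names(ctx)[vapply(ctx, function(cc) {
            all(c(v$trait, v$exposure) %in% cc)
          }, logical(1))]
          s <- s[s$cpg_id %in% ok, , drop = FALSE]
        }
        cpgs <- sort(unique(s$cpg_id))
      } else {
        cpgs <- sort(unique(pairs$cpg_id[pairs$variant_id == v$variant_id]))
      }
      if (!length(cpgs)) return(NULL)
      data.frame(ancestry_group = v$ancestry_group, trait = v$trait,
                 exposure = v$exposure, gene_id = w$gene_id[j],
                 variant_id = v$variant_id,
                 cpg_ids = paste(cpgs, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  key <- interaction(rows$gene_id, rows$ancestry_group, rows$trait,
                     rows$exposure, drop = TRUE)
  loci <- do.call(rbind, lapply(split(rows, key), function(h) {
    vids <- sort(unique(h$variant_id))
    cpgs <- sort(unique(unlist(strsplit(h$cpg_ids, ","))))
    data.frame(ancestry_group = h$ancestry_group[1], trait = h$trait[1],
               exposure = h$exposure[1], gene_id = h$gene_id[1],
               tier = "candidate", n_variants = length(vids),
               variant_ids = paste(vids, collapse = ","),
               cpg_ids = paste(cpgs, collapse = ","),
               eqtl_tissues = "", stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  order_loci(loci)
}

#' Run the full evidence-prioritization cascade
#'
#' Composes the tiers: candidate loci (a screened GLI variant inside a gene's
#' 500 kb window together with a context-matching significant DMe site in the
#' same window), prioritized loci (a variant-CpG pair where the variant is a
#' significant eQTL and the CpG a significant eQTM for the same gene, the gene
#' being a candidate in that context), and further prioritized loci
#' (additionally a significant DExpr record for the exposure class). Emits
#' per-step counts, including both conventions for the candidate-gene count
#' (DMe site in the gene window vs. DMe site within `flank` of the variant).
#'
#' @param selected Selected-variant data.frame (see
#'   [select_gli_variants()] / [scenario_selected_variants()]); an optional
#'   `p_joint` column drives the 2df association flag.
#' @param evidence List with `dme`, `eqtm`, `eqtl`, `dexpr` tables (see
#'   [generate_evidence_tables()]).
#' @param annotation Exon-level gene annotation (1-based inclusive).
#' @param genome Declared genome (`chrom`, `length`).
#' @param flank Window/pairing flank in bp; default 500000.
#' @param context_mode DMe context matching, `"or"` (default) or `"and"`.
#' @param joint_alpha Threshold on `p_joint` for flagging loci whose
#'   supporting variants also show a 2df joint association; default 5e-8.
#' @return Object of class `gli_loci`: `loci` (tiered table, one row per
#'   gene x context at its highest tier, with `dexpr_flag` and
#'   `joint2df_flag`), `counts` (per-step record counts), `pairs`
#'   (variant-CpG pairs), `windows` (gene windows used).
#' @export
run_cascade <- function(selected, evidence, annotation, genome,
                        flank = 500000L, context_mode = c("or", "and"),
                        joint_alpha = 5e-8) {
  context_mode <- match.arg(context_mode)
  windows <- gene_windows(annotation, genome, flank)
  pairs <- find_dnam_near_variants(selected, evidence$dme, flank,
                                   context_mode)
  cand <- candidate_loci(selected, evidence$dme, windows, pairs, flank,
                         context_mode, dme_scope = "gene_window")
  cand_cpg <- candidate_loci(selected, evidence$dme, windows, pairs, flank,
                             context_mode, dme_scope = "cpg_window")
  prio <- prioritize(pairs, evidence$eqtl, evidence$eqtm)
  # prioritization operates on candidate regions: keep gene-context rows that
  # are candidates
  ckey <- paste(cand$gene_id, cand$ancestry_group, cand$trait, cand$exposure)
  pkey <- paste(prio$gene_id, prio$ancestry_group, prio$trait, prio$exposure)
  prio <- prio[pkey %in% ckey, , drop = FALSE]
  further <- further_prioritize(prio, evidence$dexpr)

  loci <- cand
  loci$dexpr_flag <- logical(nrow(cand))
  loci$joint2df_flag <- logical(nrow(cand))
  pkey <- paste(prio$gene_id, prio$ancestry_group, prio$trait, prio$exposure)
  fkey <- paste(further$gene_id, further$ancestry_group, further$trait,
                further$exposure)
  lkey <- paste(loci$gene_id, loci$ancestry_group, loci$trait, loci$exposure)
  m <- match(lkey, pkey)
  hit <- !is.na(m)
  loci$tier[hit] <- "prioritized"
  loci$n_variants[hit] <- prio$n_variants[m[hit]]
  loci$variant_ids[hit] <- prio$variant_ids[m[hit]]
  loci$cpg_ids[hit] <- prio$cpg_ids[m[hit]]
  loci$eqtl_tissues[hit] <- prio$eqtl_tissues[m[hit]]
  loci$tier[lkey %in% fkey] <- "further_prioritized"
  loci$dexpr_flag <- lkey %in% fkey
  if ("p_joint" %in% names(selected)) {
    for (i in seq_len(nrow(loci))) {
      vids <- strsplit(loci$variant_ids[i], ",")[[1]]
      sel <- selected[selected$variant_id %in% vids &
                        selected$trait == loci$trait[i] &
                        selected$exposure == loci$exposure[i] &
                        selected$ancestry_group == loci$ancestry_group[i], ]
      loci$joint2df_flag[i] <- any(sel$p_joint < joint_alpha, na.rm = TRUE)
    }
  }
  loci <- order_loci(loci)
  rownames(loci) <- NULL

  counts <- list(
    n_selected_variants = length(unique(selected$variant_id)),
    n_variant_cpg_pairs = nrow(pairs),
    n_candidate_genes = length(unique(cand$gene_id)),
    n_candidate_genes_cpg_convention = length(unique(cand_cpg$gene_id)),
    n_candidate_loci = nrow(cand),
    n_prioritized_loci = nrow(prio),
    n_further_prioritized_loci = nrow(further)
  )
  structure(list(loci = loci, counts = counts, pairs = pairs,
                 windows = windows),
            class = "gli_loci")
}

#' @export
print.gli_loci <- function(x, ...) {
  cat("GLI evidence cascade result\n")
  cat(sprintf("  selected variants: %d; variant-CpG pairs: %d\n",
              x$counts$n_selected_variants, x$counts$n_variant_cpg_pairs))
  cat(sprintf(
    "  candidate genes: %d (gene-window) / %d (CpG-window convention)\n",
    x$counts$n_candidate_genes, x$counts$n_candidate_genes_cpg_convention))
  cat(sprintf("  prioritized loci: %d; further prioritized: %d\n",
              x$counts$n_prioritized_loci,
              x$counts$n_further_prioritized_loci))
  invisible(x)
}

#' @export
summary.gli_loci <- function(object, ...) {
  pr <- object$loci[object$loci$tier %in%
                      c("prioritized", "further_prioritized"), , drop = FALSE]
  summarize_loci(pr)
}
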