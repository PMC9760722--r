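# Independent brute-force oracles (base R only, no package internals) and
# small scenario builders shared across test files.

# linear-scan point query over a window table
scan_query <- function(windows, chrom, pos) {
  windows[windows$chrom == chrom & windows$window_start <= pos &
            windows$window_end >= pos, , drop = FALSE]
}

# nested-loop re-implementation of the evidence cascade; returns sets of
# "gene|ancestry|trait|exposure" keys per tier
oracle_cascade <- function(selected, evidence, windows, flank = 500000) {
  dme <- evidence$dme; eqtm <- evidence$eqtm
  eqtl <- evidence$eqtl; dexpr <- evidence$dexpr
  ctx_key <- function(g, v) paste(g, v$ancestry_group, v$trait, v$exposure,
                                  sep = "|")
  pairs <- list()
  for (i in seq_len(nrow(selected))) {
    v <- selected[i, ]
    for (j in seq_len(nrow(dme))) {
      d <- dme[j, ]
      if (d$significant && d$chrom == v$chrom &&
          abs(d$pos - v$pos) <= flank &&
          d$context %in% c(v$trait, v$exposure)) {
        pairs[[length(pairs) + 1L]] <- list(v = v, cpg = d)
      }
    }
  }
  candidate <- character(0)
  for (i in seq_len(nrow(selected))) {
    v <- selected[i, ]
    for (w in seq_len(nrow(windows))) {
      if (windows$chrom[w] == v$chrom &&
          v$pos >= windows$window_start[w] &&
          v$pos <= windows$window_end[w]) {
        for (j in seq_len(nrow(dme))) {
          d <- dme[j, ]
          if (d$significant && d$chrom == windows$chrom[w] &&
              d$pos >= windows$window_start[w] &&
              d$pos <= windows$window_end[w] &&
              d$context %in% c(v$trait, v$exposure)) {
            candidate <- c(candidate, ctx_key(windows$gene_id[w], v))
          }
        }
      }
    }
  }
  candidate <- unique(candidate)
  prioritized <- character(0)
  for (p in pairs) {
    for (a in seq_len(nrow(eqtl))) {
      if (!eqtl$significant[a] || eqtl$variant_id[a] != p$v$variant_id) next
      for (b in seq_len(nrow(eqtm))) {
        if (!eqtm$significant[b] || eqtm$cpg_id[b] != p$cpg$cpg_id) next
        if (eqtl$gene_id[a] == eqtm$gene_id[b]) {
          k <- ctx_key(eqtl$gene_id[a], p$v)
          if (k %in% candidate) prioritized <- c(prioritized, k)
        }
      }
    }
  }
  prioritized <- unique(prioritized)
  further <- character(0)
  cls <- function(e) {
    if (e %in% c("current smoking", "ever smoking")) "smoking" else "alcohol"
  }
  for (k in prioritized) {
    f <- strsplit(k, "|", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(dexpr))) {
      d <- dexpr[j, ]
      dc <- if (d$exposure %in% c("smoking", "alcohol")) d$exposure
            else cls(d$exposure)
      if (d$significant && d$gene_id == f[1] && dc == cls(f[4])) {
        further <- c(further, k)
      }
    }
  }
  list(candidate = sort(candidate), prioritized = sort(prioritized),
       further = sort(unique(further)))
}

loci_keys <- function(loci, tiers) {
  l <- loci[loci$tier %in% tiers, , drop = FALSE]
  sort(paste(l$gene_id, l$ancestry_group, l$trait, l$exposure, sep = "|"))
}

# standard planted scenario: 3 causal genes, 4 single-link decoys
make_scenario <- function(seed, trait = "HDL", exposure = "current smoking",
                          ancestry_group = "AA",
                          decoys = c(d1 = "DMe", d2 = "eQTM", d3 = "eQTL",
                                     d4 = "DExpr")) {
  genes <- c(paste0("c", 1:3), names(decoys))
  assign <- stats::setNames(genes, paste0("rs", seq_along(genes)))
  truth <- scenario_truth(causal_genes = paste0("c", 1:3),
                          decoy_genes = decoys,
                          variant_gene_assignments = assign)
  evidence <- generate_evidence_tables(truth, synthetic_genome(), seed = seed,
                                       trait = trait, exposure = exposure)
  selected <- scenario_selected_variants(truth, evidence, trait = trait,
                                         exposure = exposure,
                                         ancestry_group = ancestry_group,
                                         seed = seed)
  list(truth = truth, evidence = evidence, selected = selected)
}
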