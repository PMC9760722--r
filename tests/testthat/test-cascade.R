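toy_selected <- function(pos = 1000000L, trait = "HDL",
                         exposure = "current smoking") {
  data.frame(variant_id = "rs1", chrom = "chr1", pos = pos, trait = trait,
             exposure = exposure, ancestry_group = "AA", p_int = 1e-6,
             stringsAsFactors = FALSE)
}

toy_dme <- function(pos, context = "current smoking", significant = TRUE,
                    cpg_id = "cg1") {
  data.frame(cpg_id = cpg_id, chrom = "chr1", pos = pos, context = context,
             effect_direction = "up", p = 1e-8, significant = significant,
             stringsAsFactors = FALSE)
}

test_that("variant-CpG pairing enforces context, chromosome and distance", {
  sel <- toy_selected(pos = 1000000L)
  # matching exposure context at 400 kb: paired
  p1 <- find_dnam_near_variants(sel, toy_dme(1400000L))
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$distance, 400000L)
  # trait context also qualifies under OR matching
  p2 <- find_dnam_near_variants(sel, toy_dme(1400000L, context = "HDL"))
  expect_identical(nrow(p2), 1L)
  # wrong context: not paired
  p3 <- find_dnam_near_variants(sel, toy_dme(1400000L, context = "SBP"))
  expect_identical(nrow(p3), 0L)
  # boundary: 500,000 inside, 500,001 outside
  expect_identical(nrow(find_dnam_near_variants(sel, toy_dme(1500000L))), 1L)
  expect_identical(nrow(find_dnam_near_variants(sel, toy_dme(1500001L))), 0L)
  # non-significant sites never pair
  p4 <- find_dnam_near_variants(sel, toy_dme(1400000L, significant = FALSE))
  expect_identical(nrow(p4), 0L)
})

test_that("AND-mode context matching requires both trait and exposure", {
  sel <- toy_selected()
  # the same CpG is significant for both the exposure and the trait: one pair
  both <- rbind(toy_dme(1400000L, context = "current smoking"),
                toy_dme(1400000L, context = "HDL"))
  expect_identical(
    nrow(find_dnam_near_variants(sel, both, context_mode = "and")), 1L)
  # a CpG significant for the exposure only does not qualify under AND
  one <- toy_dme(1400000L, context = "current smoking")
  expect_identical(
    nrow(find_dnam_near_variants(sel, one, context_mode = "and")), 0L)
  # ... but still qualifies under the default OR matching
  expect_identical(
    nrow(find_dnam_near_variants(sel, one, context_mode = "or")), 1L)
})

test_that("prioritization requires the eQTL AND eQTM conjunction", {
  pairs <- find_dnam_near_variants(toy_selected(), toy_dme(1400000L))
  eqtl <- data.frame(variant_id = "rs1", gene_id = "g1", tissue = "Lung",
                     slope = 0.4, p = 1e-9, significant = TRUE)
  eqtm <- data.frame(cpg_id = "cg1", gene_id = "g1", p = 1e-9,
                     significant = TRUE)
  loc <- prioritize(pairs, eqtl, eqtm)
  expect_identical(nrow(loc), 1L)
  expect_identical(loc$gene_id, "g1")
  expect_identical(loc$n_variants, 1L)
  expect_identical(loc$eqtl_tissues, "Lung")

  # eQTL without eQTM: absent
  no_eqtm <- eqtm; no_eqtm$significant <- FALSE
  expect_identical(nrow(prioritize(pairs, eqtl, no_eqtm)), 0L)
  # eQTM without eQTL: absent
  no_eqtl <- eqtl; no_eqtl$significant <- FALSE
  expect_identical(nrow(prioritize(pairs, no_eqtl, eqtm)), 0L)
})

test_that("variants sharing a gene aggregate into one locus", {
  sel <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(variant_id = paste0("rs", i), chrom = "chr1",
               pos = 1000000L + i * 1000L, trait = "HDL",
               exposure = "current smoking", ancestry_group = "AA",
               p_int = 1e-6, stringsAsFactors = FALSE)
  }))
  pairs <- find_dnam_near_variants(sel, toy_dme(1200000L))
  eqtl <- data.frame(variant_id = paste0("rs", 1:4), gene_id = "g1",
                     tissue = c("Artery Aorta", "Testis", "Artery Aorta",
                                "Testis"),
                     slope = 0.2, p = 1e-9, significant = TRUE)
  eqtm <- data.frame(cpg_id = "cg1", gene_id = "g1", p = 1e-9,
                     significant = TRUE)
  loc <- prioritize(pairs, eqtl, eqtm)
  expect_identical(nrow(loc), 1L)
  expect_identical(loc$n_variants, 4L)
  expect_identical(loc$eqtl_tissues, "Artery Aorta,Testis")
})

test_that("differential-expression matching is at exposure-class level", {
  prio <- data.frame(ancestry_group = "AA", trait = "HDL",
                     exposure = "ever smoking", gene_id = "g1",
                     tier = "prioritized", n_variants = 1L,
                     variant_ids = "rs1", cpg_ids = "cg1",
                     eqtl_tissues = "Lung", stringsAsFactors = FALSE)
  smoking_dx <- data.frame(gene_id = "g1", exposure = "smoking",
                           direction = "up", p = 1e-5, significant = TRUE)
  out <- further_prioritize(prio, smoking_dx)
  expect_identical(nrow(out), 1L)
  expect_identical(out$tier, "further_prioritized")

  # full exposure labels in the DExpr table also map through their class
  full_dx <- data.frame(gene_id = "g1", exposure = "current smoking",
                        direction = "up", p = 1e-5, significant = TRUE)
  expect_identical(nrow(further_prioritize(prio, full_dx)), 1L)

  # an alcohol-exposure locus with only smoking DExpr evidence never promotes
  alc <- prio; alc$exposure <- "current drinking"
  expect_identical(nrow(further_prioritize(alc, smoking_dx)), 0L)

  expect_identical(nrow(further_prioritize(prio[0, ], smoking_dx)), 0L)
})

test_that("the cascade recovers planted causal genes and rejects decoys", {
  for (seed in c(101, 202, 303)) {
    sc <- make_scenario(seed)
    res <- run_cascade(sc$selected, sc$evidence, sc$evidence$annotation,
                       synthetic_genome())
    prio_genes <- unique(res$loci$gene_id[
      res$loci$tier %in% c("prioritized", "further_prioritized")])
    further_genes <- unique(res$loci$gene_id[
      res$loci$tier == "further_prioritized"])
    # full cascade: exactly the causal genes
    expect_setequal(further_genes, sc$truth$causal_genes)
    # the DExpr decoy passes the eQTL+eQTM conjunction but not DExpr
    expect_setequal(prio_genes, c(sc$truth$causal_genes, "d4"))
    # eQTM decoy: present after the DMe-overlap step, absent after
    # prioritization
    cand_genes <- unique(res$loci$gene_id)
    expect_true("d2" %in% cand_genes)
    expect_false("d2" %in% prio_genes)
  }
})

test_that("the cascade matches the brute-force nested-loop join oracle", {
  for (seed in c(7, 19, 31, 57)) {
    sc <- make_scenario(seed)
    res <- run_cascade(sc$selected, sc$evidence, sc$evidence$annotation,
                       synthetic_genome())
    oracle <- oracle_cascade(sc$selected, sc$evidence, res$windows)
    expect_identical(loci_keys(res$loci, c("candidate", "prioritized",
                                           "further_prioritized")),
                     oracle$candidate)
    expect_identical(loci_keys(res$loci, c("prioritized",
                                           "further_prioritized")),
                     oracle$prioritized)
    expect_identical(loci_keys(res$loci, "further_prioritized"),
                     oracle$further)
  }
})

test_that("tiers nest and evidence removal is monotone", {
  sc <- make_scenario(404)
  res <- run_cascade(sc$selected, sc$evidence, sc$evidence$annotation,
                     synthetic_genome())
  keys <- function(tiers) loci_keys(res$loci, tiers)
  expect_true(all(keys("further_prioritized") %in%
                    keys(c("prioritized", "further_prioritized"))))
  expect_true(all(keys(c("prioritized", "further_prioritized")) %in%
                    keys(c("candidate", "prioritized",
                           "further_prioritized"))))

  # removing the eQTM table collapses the prioritized tier
  ev2 <- sc$evidence
  ev2$eqtm$significant <- FALSE
  res2 <- run_cascade(sc$selected, ev2, sc$evidence$annotation,
                      synthetic_genome())
  expect_identical(
    nrow(res2$loci[res2$loci$tier != "candidate", , drop = FALSE]), 0L)

  # removing DMe rows never adds loci
  ev3 <- sc$evidence
  ev3$dme <- ev3$dme[-1, , drop = FALSE]
  res3 <- run_cascade(sc$selected, ev3, sc$evidence$annotation,
                      synthetic_genome())
  expect_true(all(loci_keys(res3$loci, unique(res3$loci$tier)) %in%
                    loci_keys(res$loci, unique(res$loci$tier))))

  # adding an evidence row never removes a locus
  ev4 <- sc$evidence
  extra <- ev4$dme[1, ]
  extra$cpg_id <- "cg_extra"
  extra$pos <- extra$pos + 1000L
  ev4$dme <- rbind(ev4$dme, extra)
  res4 <- run_cascade(sc$selected, ev4, sc$evidence$annotation,
                      synthetic_genome())
  expect_true(all(loci_keys(res$loci, unique(res$loci$tier)) %in%
                    loci_keys(res4$loci, unique(res4$loci$tier))))
})

test_that("the cascade is deterministic", {
  sc <- make_scenario(777)
  r1 <- run_cascade(sc$selected, sc$evidence, sc$evidence$annotation,
                    synthetic_genome())
  r2 <- run_cascade(sc$selected, sc$evidence, sc$evidence$annotation,
                    synthetic_genome())
  expect_identical(r1$loci, r2$loci)
  expect_identical(r1$counts, r2$counts)
})

test_that("context discipline: loci only carry their variants' contexts", {
  sc <- make_scenario(88, trait = "TG", exposure = "current drinking",
                      ancestry_group = "EA")
  res <- run_cascade(sc$selected, sc$evidence, sc$evidence$annotation,
                     synthetic_genome())
  expect_true(all(res$loci$trait == "TG"))
  expect_true(all(res$loci$exposure == "current drinking"))
  expect_true(all(res$loci$ancestry_group == "EA"))
})
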