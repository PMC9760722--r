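#' Configuration for an end-to-end prioritization run
#'
#' Bundles the planted truth, the simulated study design and every analysis
#' threshold. All thresholds default to the values the pipeline's analysis
#' stages document: 500 kb flank, interaction screen 5e-5, MAF filter 1%,
#' heterogeneity filter 1e-6, OR-mode DMe context matching.
#'
#' @param seed Global seed; every cohort and table derives its own substream
#'   from it, so adding a cohort does not perturb the others' draws.
#' @param truth A [scenario_truth()]; default: three causal genes and four
#'   single-link decoys (DMe, eQTM, eQTL, DExpr) plus one decoy with no
#'   interaction signal.
#' @param genome A [synthetic_genome()].
#' @param trait,exposure Analysis-set context for the simulated study.
#' @param ancestries Ancestry label per simulated cohort (length = number of
#'   cohorts).
#' @param n_per_cohort Individuals per cohort.
#' @param beta_GL Planted interaction effect at signal variants.
#' @param beta_G Planted genetic main effect.
#' @param eaf,exposure_prev,noise_sd Generative parameters
#'   (see [gli_params()]).
#' @param flank Locus flank in bp.
#' @param alpha Interaction-significance screen.
#' @param maf_min,het_alpha QC thresholds.
#' @param context_mode DMe context matching mode (`"or"`/`"and"`).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       truth = scenario_truth(
                         causal_genes = c("GENE1", "GENE2", "GENE3"),
                         decoy_genes = c(GENE4 = "DMe", GENE5 = "eQTM",
                                         GENE6 = "eQTL", GENE7 = "DExpr",
                                         GENE8 = "GLI-signal"),
                         variant_gene_assignments = c(
                           rs101 = "GENE1", rs102 = "GENE2", rs103 = "GENE3",
                           rs104 = "GENE4", rs105 = "GENE5", rs106 = "GENE6",
                           rs107 = "GENE7", rs108 = "GENE8")),
                       genome = synthetic_genome(),
                       trait = "HDL", exposure = "current smoking",
                       ancestries = c("AA", "AA", "EA", "EA", "ASA"),
                       n_per_cohort = 4000L,
                       beta_GL = 0.15, beta_G = 0.1,
                       eaf = 0.3, exposure_prev = 0.4, noise_sd = 1,
                       flank = 500000L, alpha = 5e-5,
                       maf_min = 0.01, het_alpha = 1e-6,
                       context_mode = "or") {
  stopifnot(inherits(truth, "scenario_truth"))
  if (alpha <= 0 || alpha >= 1 || maf_min < 0 || maf_min >= 0.5 ||
      het_alpha <= 0 || het_alpha >= 1 || flank < 0) {
    stop_gliprio("invalid_threshold", "threshold outside its valid range")
  }
  structure(list(seed = as.integer(seed), truth = truth, genome = genome,
                 trait = trait, exposure = exposure, ancestries = ancestries,
                 n_per_cohort = as.integer(n_per_cohort),
                 beta_GL = beta_GL, beta_G = beta_G, eaf = eaf,
                 exposure_prev = exposure_prev, noise_sd = noise_sd,
                 flank = as.integer(flank), alpha = alpha,
                 maf_min = maf_min, het_alpha = het_alpha,
                 context_mode = context_mode),
            class = "run_config")
}

#' Write / read a run configuration as structured text
#'
#' The effective configuration is echoed as JSON so a run can be reproduced
#' from its run directory alone.
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `write_run_config` returns `path`; `read_run_config` returns the
#'   reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$truth <- list(causal_genes = config$truth$causal_genes,
                  decoy_genes = as.list(config$truth$decoy_genes),
                  variant_gene_assignments =
                    as.list(config$truth$variant_gene_assignments))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- scenario_truth(
    causal_genes = unlist(x$truth$causal_genes),
    decoy_genes = unlist(x$truth$decoy_genes),
    variant_gene_assignments = unlist(x$truth$variant_gene_assignments))
  run_config(seed = x$seed, truth = truth,
             genome = as.data.frame(x$genome),
             trait = x$trait, exposure = x$exposure,
             ancestries = unlist(x$ancestries),
             n_per_cohort = x$n_per_cohort, beta_GL = x$beta_GL,
             beta_G = x$beta_G, eaf = x$eaf,
             exposure_prev = x$exposure_prev, noise_sd = x$noise_sd,
             flank = x$flank, alpha = x$alpha, maf_min = x$maf_min,
             het_alpha = x$het_alpha, context_mode = x$context_mode)
}

#' Execute the full pipeline: simulate, meta-analyze, select, prioritize,
#' report
#'
#' Runs every stage on the configured synthetic study, optionally writing all
#' stage outputs, a structured per-stage count log and an exact echo of the
#' effective configuration to a run directory. Fully deterministic given the
#' configuration seed.
#'
#' @param config A [run_config()] object.
#' @param out_dir Run directory to write stage outputs into; `NULL` to skip
#'   writing.
#' @return Object of class `gli_run`: `config`, `cohort_stats`, `meta`,
#'   `exclusions`, `selected`, `cascade` (a `gli_loci`), `summary`
#'   (a `locus_summary` over tiers >= prioritized), `log` (per-stage counts).
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 7), out_dir = NULL)
#' run$log
#' summary(run$cascade)
#' }
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  evidence <- generate_evidence_tables(config$truth, config$genome,
                                       seed = config$seed,
                                       trait = config$trait,
                                       exposure = config$exposure)
  silent <- names(config$truth$decoy_genes)[
    config$truth$decoy_genes == "GLI-signal"]

  # stage 1: per-cohort simulation and OLS fits at every planted variant
  stats_list <- list()
  for (i in seq_len(nrow(evidence$variants))) {
    v <- evidence$variants[i, ]
    b_gl <- if (v$gene_id %in% silent) 0 else config$beta_GL
    params <- gli_params(beta_G = config$beta_G, beta_GL = b_gl,
                         beta_C = c(0.2, -0.1), noise_sd = config$noise_sd,
                         eaf = config$eaf,
                         exposure_prev = config$exposure_prev)
    for (j in seq_along(config$ancestries)) {
      cid <- sprintf("cohort%02d", j)
      spec <- cohort_spec(cid, config$n_per_cohort, config$ancestries[j],
                          config$trait, config$exposure,
                          seed = substream_seed(config$seed,
                                                paste(cid, v$variant_id)))
      stats_list[[length(stats_list) + 1L]] <-
        simulate_cohort_stats(params, spec, variant_id = v$variant_id,
                              chrom = v$chrom, pos = v$pos)
    }
  }
  cohort_stats <- do.call(rbind, stats_list)

  # stage 2: two-stage meta-analysis and QC
  meta <- meta_analyze(cohort_stats)
  qc <- qc_filter(meta, maf_min = config$maf_min,
                  het_alpha = config$het_alpha)

  # stage 3: interaction-significance screen
  selected <- select_gli_variants(qc$records, alpha = config$alpha)

  # stage 4: evidence cascade
  cascade <- run_cascade(selected, evidence, evidence$annotation,
                         config$genome, flank = config$flank,
                         context_mode = config$context_mode)

  # stage 5: reporting
  pr <- cascade$loci[cascade$loci$tier %in%
                       c("prioritized", "further_prioritized"), ,
                     drop = FALSE]
  summ <- summarize_loci(pr)
  log <- c(list(n_cohort_records = nrow(cohort_stats),
                n_meta_records = nrow(meta),
                n_qc_excluded = nrow(qc$exclusions),
                n_qc_retained = nrow(qc$records),
                n_selected_records = nrow(selected)),
           cascade$counts)

  run <- structure(list(config = config, cohort_stats = cohort_stats,
                        meta = qc$records, exclusions = qc$exclusions,
                        selected = selected, cascade = cascade,
                        summary = summ, log = log),
                   class = "gli_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) {
      utils::write.table(x, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_run_config(config, file.path(out_dir, "config.json"))
    wt(cohort_stats, "cohort_stats.tsv")
    wt(qc$records, "meta.tsv")
    wt(qc$exclusions, "exclusions.tsv")
    wt(selected, "selected.tsv")
    wt(cascade$loci, "loci.tsv")
    wt(cascade$pairs, "pairs.tsv")
    write_gene_bed(evidence$annotation, file.path(out_dir, "genes.bed"))
    wt(evidence$dme, "dme.tsv")
    wt(evidence$eqtm, "eqtm.tsv")
    wt(evidence$eqtl, "eqtl.tsv")
    wt(evidence$dexpr, "dexpr.tsv")
    writeLines(format_locus_report(cascade$loci),
               file.path(out_dir, "report.txt"))
    jsonlite::write_json(log, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.gli_run <- function(x, ...) {
  cat("GLI prioritization run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  cohort records: %d; meta records kept: %d (excluded %d)\n",
              x$log$n_cohort_records, x$log$n_qc_retained,
              x$log$n_qc_excluded))
  cat(sprintf("  selected records: %d\n", x$log$n_selected_records))
  print(x$cascade)
  invisible(x)
}
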