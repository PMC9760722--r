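#' Summarize a tiered locus table
#'
#' Computes the count surfaces used to describe a prioritized-locus set:
#' totals, counts and percentage shares by ancestry group, counts by exposure
#' class (smoking vs. alcohol) and trait class (lipids vs. blood pressure),
#' the ancestry x exposure-class cross-tabulation, and the number of distinct
#' genes carrying a differential-expression flag.
#'
#' @param loci data.frame with columns `ancestry_group`, `trait`, `exposure`,
#'   `gene_id`, `dexpr_flag` (rows are loci, i.e. gene x context records).
#' @return Object of class `locus_summary`.
#' @examples
#' summarize_loci(published_prioritized_loci())
#' @export
summarize_loci <- function(loci) {
  if (nrow(loci)) {
    ec <- exposure_class(loci$exposure)  # validates vocab
    tc <- trait_class(loci$trait)
    bad <- setdiff(unique(loci$ancestry_group), gli_ancestry_groups())
    if (length(bad)) {
      stop_gliprio("vocabulary_violation", "unknown ancestry group(s): ",
                   paste(bad, collapse = ", "))
    }
  } else {
    ec <- character(0); tc <- character(0)
  }
  tab <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))
  }
  by_anc <- tab(loci$ancestry_group)
  structure(list(
    total_loci = nrow(loci),
    by_ancestry_group = by_anc,
    by_exposure_class = tab(ec),
    by_trait_class = tab(tc),
    fraction_by_ancestry = if (nrow(loci)) {
      round(100 * by_anc / nrow(loci), 1)
    } else {
      stats::setNames(numeric(0), character(0))
    },
    n_distinct_dexpr_genes = length(unique(loci$gene_id[loci$dexpr_flag])),
    cross_tabs = if (nrow(loci)) {
      table(ancestry_group = loci$ancestry_group, exposure_class = ec)
    } else {
      table(ancestry_group = character(0), exposure_class = character(0))
    }
  ), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat("Prioritized-locus summary\n")
  cat("  total loci:", x$total_loci, "\n")
  if (length(x$by_ancestry_group)) {
    cat("  by ancestry group:",
        paste(names(x$by_ancestry_group), x$by_ancestry_group,
              sep = "=", collapse = ", "), "\n")
    cat("  ancestry shares (%):",
        paste(names(x$fraction_by_ancestry), x$fraction_by_ancestry,
              sep = "=", collapse = ", "), "\n")
  }
  if (length(x$by_exposure_class)) {
    cat("  by exposure class:",
        paste(names(x$by_exposure_class), x$by_exposure_class,
              sep = "=", collapse = ", "), "\n")
  }
  if (length(x$by_trait_class)) {
    cat("  by trait class:",
        paste(names(x$by_trait_class), x$by_trait_class,
              sep = "=", collapse = ", "), "\n")
  }
  cat("  distinct DExpr-flagged genes:", x$n_distinct_dexpr_genes, "\n")
  invisible(x)
}

.ancestry_headings <- c(AA = "African Ancestry", ASA = "Asian Ancestry",
                        EA = "European Ancestry", HA = "Hispanic Ancestry",
                        TRANS = "Trans Ancestry")

#' Format a prioritized-locus table as a fixed-width report
#'
#' Rows at tier prioritized or above, grouped under ancestry x trait headings,
#' with abbreviated exposure labels, eQTL tissues and the number of supporting
#' GLI variants. Genes flagged `*` show differential expression by the
#' exposure class; genes flagged `^` also carry a 2df joint association.
#' Output is deterministic for identical input.
#'
#' @param loci Tiered locus data.frame (columns as in [run_cascade()]'s
#'   `loci`, at minimum ancestry_group, trait, exposure, gene_id, tier,
#'   n_variants, eqtl_tissues, dexpr_flag, joint2df_flag).
#' @return Character vector of report lines.
#' @examples
#' cat(head(format_locus_report(published_prioritized_loci()), 8), sep = "\n")
#' @export
format_locus_report <- function(loci) {
  loci <- loci[loci$tier %in% c("prioritized", "further_prioritized"), ,
               drop = FALSE]
  lines <- c("Prioritized loci",
             sprintf("%-12s  %-22s  %-50s  %s",
                     "Exposure", "Gene target", "eQTL Tissue(s)",
                     "N GLI variants"))
  if (!nrow(loci)) return(lines)
  loci <- order_loci(loci)
  anc_order <- intersect(names(.ancestry_headings),
                         unique(loci$ancestry_group))
  for (anc in anc_order) {
    la <- loci[loci$ancestry_group == anc, , drop = FALSE]
    for (tr in unique(la$trait)) {
      lt <- la[la$trait == tr, , drop = FALSE]
      lines <- c(lines, sprintf("-- %s %s --", .ancestry_headings[[anc]], tr))
      for (i in seq_len(nrow(lt))) {
        gene <- paste0(lt$gene_id[i],
                       if (lt$dexpr_flag[i]) "*" else "",
                       if (lt$joint2df_flag[i]) "^" else "")
        tiss <- lt$eqtl_tissues[i]
        if (!nzchar(tiss)) tiss <- "-"
        lines <- c(lines, sprintf("%-12s  %-22s  %-50s  %d",
                                  abbreviate_exposure(lt$exposure[i]), gene,
                                  gsub(",", ", ", tiss), lt$n_variants[i]))
      }
    }
  }
  lines
}

#' Parse a formatted locus report back into a locus table
#'
#' Inverse of [format_locus_report()] up to the fields the report carries
#' (tissue lists, variant counts and flags; supporting variant/CpG id lists
#' are not printed and come back empty).
#'
#' @param lines Character vector from [format_locus_report()].
#' @return Tiered locus data.frame.
#' @export
parse_locus_report <- function(lines) {
  abbr <- c("Curr Smk" = "current smoking", "Ev Smk" = "ever smoking",
            "Curr Drnk" = "current drinking", "Reg Drnk" = "regular drinking",
            "Drnk habits" = "drinking habits")
  anc_rev <- stats::setNames(names(.ancestry_headings), .ancestry_headings)
  out <- list(); anc <- NA_character_; tr <- NA_character_
  for (ln in lines) {
    h <- regmatches(ln, regexec("^-- (.+) (\\S+) --$", ln))[[1]]
    if (length(h) == 3L) {
      anc <- anc_rev[[h[2]]]; tr <- h[3]
      next
    }
    f <- strsplit(trimws(ln), "  +")[[1]]
    if (length(f) != 4L || !f[1] %in% names(abbr)) next
    gene <- f[2]
    dexpr <- grepl("\\*", gene)
    joint <- grepl("\\^", gene)
    gene <- gsub("[*^]", "", gene)
    tiss <- if (f[3] == "-") "" else gsub(", ", ",", f[3])
    out[[length(out) + 1L]] <- data.frame(
      ancestry_group = anc, trait = tr, exposure = abbr[[f[1]]],
      gene_id = gene,
      tier = if (dexpr) "further_prioritized" else "prioritized",
      n_variants = as.integer(f[4]), variant_ids = "", cpg_ids = "",
      eqtl_tissues = tiss, dexpr_flag = dexpr, joint2df_flag = joint,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(ancestry_group = character(0), trait = character(0),
                      exposure = character(0), gene_id = character(0),
                      tier = character(0), n_variants = integer(0),
                      variant_ids = character(0), cpg_ids = character(0),
                      eqtl_tissues = character(0), dexpr_flag = logical(0),
                      joint2df_flag = logical(0)))
  }
  do.call(rbind, out)
}

#' Selection-report tables from a variant tally
#'
#' @param tally A [tally_selection()] object.
#' @return List with `classes` (long-format unique-variant counts per class
#'   label) and `cells` (per trait x exposure x ancestry-group cell counts).
#' @export
selection_report <- function(tally) {
  stopifnot(inherits(tally, "gli_tally"))
  long <- function(counts, type) {
    if (!length(counts)) {
      return(data.frame(type = character(0), class = character(0),
                        n_variants = integer(0)))
    }
    data.frame(type = type, class = names(counts),
               n_variants = as.integer(counts), stringsAsFactors = FALSE)
  }
  classes <- rbind(long(tally$by_exposure_class, "exposure_class"),
                   long(tally$by_trait_class, "trait_class"),
                   long(tally$by_ancestry_group, "ancestry_group"))
  rownames(classes) <- NULL
  list(n_unique_variants = tally$n_unique_variants,
       classes = classes,
       ancestry_row_share = tally$ancestry_row_share,
       cells = tally$cells)
}

#' Reference table of published prioritized GLI loci
#'
#' A transcription of the 48 prioritized gene-lifestyle interaction loci
#' reported by the CHARGE consortium's multi-ancestry smoking/alcohol x
#' lipids/blood-pressure interaction meta-analyses after multi-omics evidence
#' prioritization, shipped as package data for regression-testing the
#' reporting surfaces. Columns match the tiered locus tables produced by
#' [run_cascade()].
#'
#' @return data.frame with 48 rows: ancestry_group, trait, exposure, gene_id,
#'   tier, n_variants, eqtl_tissues, multi_tissue (more tissues exist than
#'   listed), dexpr_flag, joint2df_flag.
#' @export
published_prioritized_loci <- function() {
  path <- system.file("extdata", "published_loci.tsv", package = "gliprio")
  loci <- utils::read.delim(path, stringsAsFactors = FALSE)
  loci$dexpr_flag <- as.logical(loci$dexpr_flag)
  loci$joint2df_flag <- as.logical(loci$joint2df_flag)
  loci$multi_tissue <- as.logical(loci$multi_tissue)
  loci
}
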