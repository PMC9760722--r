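#' Screen meta-analyzed variants on interaction significance
#'
#' Retains records whose 1df interaction p-value is strictly below `alpha`
#' (default 5e-5). A variant may qualify in several analysis sets (trait x
#' exposure x ancestry-group combinations) and is kept once per context.
#'
#' @param records MetaGliRecord data.frame (post [qc_filter()]), carrying
#'   `p_int`, `trait`, `exposure`, `ancestry_group`.
#' @param alpha Interaction-significance screen, strictly in (0, 1).
#' @return The subset of `records` with `p_int < alpha`.
#' @examples
#' \dontrun{select_gli_variants(meta$records, alpha = 5e-5)}
#' @export
select_gli_variants <- function(records, alpha = 5e-5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_gliprio("invalid_threshold", "alpha must lie strictly in (0, 1)")
  }
  if (!"p_int" %in% names(records)) {
    stop_gliprio("invalid_params", "records lack a p_int column")
  }
  records[records$p_int < alpha, , drop = FALSE]
}

#' Tally selected variants by analysis class
#'
#' Counts unique variants per exposure class (smoking/alcohol), trait class
#' (lipids/blood pressure) and ancestry group. A variant seen in several
#' analysis sets of one class counts once in that class. Two conventions for
#' the ancestry tally are reported: per-class unique variants
#' (`by_ancestry_group`) and the share each ancestry group contributes to all
#' selected rows (`ancestry_row_share`), since published counts mix both.
#'
#' @param selected Selected-variant data.frame from [select_gli_variants()].
#' @return List of class `gli_tally` with `n_unique_variants`,
#'   `by_exposure_class`, `by_trait_class`, `by_ancestry_group`,
#'   `ancestry_row_share` (percentages), and `cells` (unique-variant counts
#'   per trait x exposure x ancestry-group cell).
#' @export
tally_selection <- function(selected) {
  count_by <- function(cls) {
    if (!nrow(selected)) return(integer(0))
    vapply(split(selected$variant_id, cls),
           function(v) length(unique(v)), integer(1))
  }
  n_unique <- length(unique(selected$variant_id))
  by_exp <- count_by(if (nrow(selected)) exposure_class(selected$exposure)
                     else character(0))
  by_trait <- count_by(if (nrow(selected)) trait_class(selected$trait)
                       else character(0))
  by_anc <- count_by(selected$ancestry_group)
  share <- if (nrow(selected)) {
    100 * table(selected$ancestry_group) / nrow(selected)
  } else {
    table(character(0))
  }
  cells <- if (nrow(selected)) {
    agg <- stats::aggregate(
      variant_id ~ trait + exposure + ancestry_group, data = selected,
      FUN = function(v) length(unique(v)))
    names(agg)[names(agg) == "variant_id"] <- "n_variants"
    agg
  } else {
    data.frame(trait = character(0), exposure = character(0),
               ancestry_group = character(0), n_variants = integer(0))
  }
  structure(list(n_unique_variants = n_unique,
                 by_exposure_class = by_exp,
                 by_trait_class = by_trait,
                 by_ancestry_group = by_anc,
                 ancestry_row_share = share,
                 cells = cells),
            class = "gli_tally")
}

#' @export
print.gli_tally <- function(x, ...) {
  cat("GLI variant selection tally\n")
  cat("  unique variants:", x$n_unique_variants, "\n")
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
  if (length(x$by_ancestry_group)) {
    cat("  by ancestry group:",
        paste(names(x$by_ancestry_group), x$by_ancestry_group,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
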