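#' Controlled vocabularies for the GLI analysis space
#'
#' The pipeline operates over a closed set of ancestry groups, quantitative
#' traits and binary lifestyle exposures. Traits split into lipid measures
#' (HDL, LDL, TG) and blood-pressure measures (SBP, DBP, MAP, PP); exposures
#' split into smoking (current/ever smoking) and alcohol (current drinking,
#' regular drinking, drinking habits) classes.
#'
#' @return A character vector of admissible labels.
#' @name gli_vocab
NULL

#' @rdname gli_vocab
#' @export
gli_ancestries <- function() c("EA", "AA", "HA", "ASA")

#' @rdname gli_vocab
#' @export
gli_ancestry_groups <- function() c(gli_ancestries(), "TRANS")

#' @rdname gli_vocab
#' @export
gli_traits <- function() c("HDL", "LDL", "TG", "SBP", "DBP", "MAP", "PP")

#' @rdname gli_vocab
#' @export
gli_exposures <- function() {
  c("current smoking", "ever smoking",
    "current drinking", "regular drinking", "drinking habits")
}

#' Map traits and exposures to their analysis classes
#'
#' @param trait Character vector of trait labels (see [gli_traits()]).
#' @param exposure Character vector of exposure labels (see [gli_exposures()]).
#' @return Character vector: `"lipids"`/`"blood pressure"` for traits,
#'   `"smoking"`/`"alcohol"` for exposures.
#' @examples
#' trait_class(c("HDL", "SBP"))
#' exposure_class("ever smoking")
#' @export
trait_class <- function(trait) {
  bad <- setdiff(unique(trait), gli_traits())
  if (length(bad)) {
    stop_gliprio("vocabulary_violation", "unknown trait label(s): ",
                 paste(bad, collapse = ", "))
  }
  ifelse(trait %in% c("HDL", "LDL", "TG"), "lipids", "blood pressure")
}

#' @rdname trait_class
#' @export
exposure_class <- function(exposure) {
  bad <- setdiff(unique(exposure), gli_exposures())
  if (length(bad)) {
    stop_gliprio("vocabulary_violation", "unknown exposure label(s): ",
                 paste(bad, collapse = ", "))
  }
  ifelse(exposure %in% c("current smoking", "ever smoking"),
         "smoking", "alcohol")
}

#' Abbreviate exposure labels for report tables
#'
#' @param exposure Character vector of exposure labels.
#' @return Abbreviations: Curr Smk, Ev Smk, Curr Drnk, Reg Drnk, Drnk habits.
#' @export
abbreviate_exposure <- function(exposure) {
  map <- c("current smoking"  = "Curr Smk",
           "ever smoking"     = "Ev Smk",
           "current drinking" = "Curr Drnk",
           "regular drinking" = "Reg Drnk",
           "drinking habits"  = "Drnk habits")
  bad <- setdiff(unique(exposure), names(map))
  if (length(bad)) {
    stop_gliprio("vocabulary_violation", "unknown exposure label(s): ",
                 paste(bad, collapse = ", "))
  }
  unname(map[exposure])
}

# Classed conditions so callers can distinguish failure modes programmatically.
stop_gliprio <- function(class, ...) {
  stop(structure(
    class = c(paste0("gliprio_", class), "gliprio_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Deterministic substream seed derived from a global seed and a string id, so
# per-cohort draws do not shift when other cohorts are added to a config.
substream_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (b in utf8ToInt(paste0(id))) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h + 1) %% 2147483647)
}
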