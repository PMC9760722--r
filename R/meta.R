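#' Align a cohort record to a canonical allele pair
#'
#' If the record's alleles match the canonical pair in swapped order, both
#' effect estimates are negated and the effect-allele frequency is reflected;
#' the covariance of (beta_G, beta_GL) is unchanged because both coefficients
#' flip sign together. Strand-ambiguous pairs (A/T, C/G) pass through but are
#' flagged in a `strand_ambiguous` column.
#'
#' @param stat A one-row CohortGliStat data.frame
#'   (see [cohort_gli_stat()]).
#' @param canonical Character vector of length 2: canonical
#'   (effect, other) alleles.
#' @return The aligned record, with a `strand_ambiguous` logical column.
#' @examples
#' rec <- simulate_cohort_stats(gli_params(),
#'   cohort_spec("c1", 500, "EA", "HDL", "ever smoking", 1))
#' align_alleles(rec, c("A", "G"))
#' @export
align_alleles <- function(stat, canonical) {
  stopifnot(length(canonical) == 2L)
  ea <- stat$effect_allele; oa <- stat$other_allele
  amb <- paste0(sort(c(ea, oa)), collapse = "/") %in% c("A/T", "C/G")
  if (ea == canonical[1] && oa == canonical[2]) {
    # already aligned
  } else if (ea == canonical[2] && oa == canonical[1]) {
    stat$beta_G <- -stat$beta_G
    stat$beta_GL <- -stat$beta_GL
    stat$eaf <- 1 - stat$eaf
    stat$effect_allele <- canonical[1]
    stat$other_allele <- canonical[2]
  } else {
    stop_gliprio("allele_mismatch",
                 "alleles (", ea, ",", oa, ") do not match canonical (",
                 canonical[1], ",", canonical[2], ") in either order")
  }
  stat$strand_ambiguous <- amb
  stat
}

#' Inverse-variance fixed-effect meta-analysis of scalar estimates
#'
#' Combines estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i b_i / \sum w_i}, \eqn{se = \sqrt{1/\sum w_i}}.
#'
#' @param beta Numeric vector of estimates.
#' @param se Numeric vector of standard errors (all > 0).
#' @return List with `beta`, `se`.
#' @examples
#' inverse_variance_meta(c(0.1, 0.2), c(0.05, 0.1))
#' @export
inverse_variance_meta <- function(beta, se) {
  if (length(beta) == 0L) {
    stop_gliprio("empty_input", "no estimates to combine")
  }
  if (length(beta) != length(se) || any(!is.finite(se)) || any(se <= 0)) {
    stop_gliprio("invalid_params", "se must be positive and match beta")
  }
  w <- 1 / se^2
  list(beta = sum(w * beta) / sum(w), se = sqrt(1 / sum(w)))
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum w_i (b_i - \hat\beta)^2} with \eqn{w_i = 1/se_i^2}, referred
#' to a chi-square distribution on k-1 degrees of freedom.
#'
#' @param beta,se Cohort estimates and standard errors (k >= 2).
#' @param beta_meta The fixed-effect combined estimate; computed from the
#'   inputs if omitted.
#' @return List with `Q`, `df`, `p`.
#' @examples
#' cochran_q(c(0.1, 0.2), c(0.05, 0.1))
#' @export
cochran_q <- function(beta, se, beta_meta = NULL) {
  if (length(beta) < 2L) {
    stop_gliprio("insufficient_cohorts",
                 "heterogeneity requires at least 2 estimates")
  }
  if (is.null(beta_meta)) beta_meta <- inverse_variance_meta(beta, se)$beta
  w <- 1 / se^2
  Q <- sum(w * (beta - beta_meta)^2)
  df <- length(beta) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Multivariate inverse-variance meta-analysis of (beta_G, beta_GL)
#'
#' Combines per-cohort bivariate estimates by summing precision
#' (inverse-covariance) matrices: the pooled precision is
#' \eqn{P = \sum_i \Sigma_i^{-1}}, the pooled estimate
#' \eqn{\hat\beta = P^{-1} \sum_i \Sigma_i^{-1} b_i}, and the 2df joint Wald
#' statistic is \eqn{\chi^2 = \hat\beta^\top P \hat\beta}, testing the null
#' that both the genetic main effect and the interaction effect are zero.
#'
#' @param beta_G,beta_GL,se_G,se_GL,cov_G_GL Per-cohort estimate vectors.
#' @return List with `beta` (length-2 pooled vector), `cov` (2x2 pooled
#'   covariance), `chi2`, `df` (= 2), `p`.
#' @examples
#' joint_2df_meta(0.1, 0.1, 0.05, 0.05, 0)
#' @export
joint_2df_meta <- function(beta_G, beta_GL, se_G, se_GL, cov_G_GL) {
  k <- length(beta_G)
  if (k == 0L) stop_gliprio("empty_input", "no cohorts to combine")
  P <- matrix(0, 2, 2)
  Pb <- c(0, 0)
  for (i in seq_len(k)) {
    Sigma <- matrix(c(se_G[i]^2, cov_G_GL[i], cov_G_GL[i], se_GL[i]^2), 2, 2)
    Pi <- tryCatch(solve(Sigma), error = function(e) NULL)
    if (is.null(Pi)) {
      stop_gliprio("singular_precision",
                   "singular (beta_G, beta_GL) covariance in cohort ", i)
    }
    P <- P + Pi
    Pb <- Pb + drop(Pi %*% c(beta_G[i], beta_GL[i]))
  }
  covm <- solve(P)
  b <- drop(covm %*% Pb)
  chi2 <- drop(t(b) %*% P %*% b)
  list(beta = stats::setNames(b, c("beta_G", "beta_GL")), cov = covm,
       chi2 = chi2, df = 2L,
       p = stats::pchisq(chi2, 2, lower.tail = FALSE))
}

# combine one group of cohort-level (or ancestry-level) records into a single
# meta record; het is computed on beta_GL over the direct inputs. The scalar
# inverse-variance channel (beta_*_meta, se_*_meta) and the multivariate
# precision-sum channel (joint_* columns, driving chi2_joint) are both
# associative and are carried separately so two-stage combination equals
# one-stage in each. At cohort level the joint_* inputs equal the scalar ones.
combine_group <- function(g, ancestry_group) {
  if (is.null(g$joint_beta_G)) {
    g$joint_beta_G <- g$beta_G; g$joint_beta_GL <- g$beta_GL
    g$joint_var_G <- g$se_G^2; g$joint_var_GL <- g$se_GL^2
    g$joint_cov <- g$cov_G_GL
  }
  m1 <- inverse_variance_meta(g$beta_GL, g$se_GL)
  mg <- inverse_variance_meta(g$beta_G, g$se_G)
  j <- joint_2df_meta(g$joint_beta_G, g$joint_beta_GL,
                      sqrt(g$joint_var_G), sqrt(g$joint_var_GL), g$joint_cov)
  if (nrow(g) >= 2L) {
    q <- cochran_q(g$beta_GL, g$se_GL, m1$beta)
    het_Q <- q$Q; het_df <- q$df; het_p <- q$p
  } else {
    het_Q <- NA_real_; het_df <- 0L; het_p <- NA_real_
  }
  z <- m1$beta / m1$se
  eaf <- sum(g$eaf * g$n) / sum(g$n)
  data.frame(
    variant_id = g$variant_id[1], chrom = g$chrom[1], pos = g$pos[1],
    effect_allele = g$effect_allele[1], other_allele = g$other_allele[1],
    pooled_eaf = eaf, pooled_maf = min(eaf, 1 - eaf),
    n_total = sum(g$n), k_cohorts = sum(g$k),
    beta_GL_meta = m1$beta, se_GL_meta = m1$se,
    p_int = 2 * stats::pnorm(-abs(z)),
    beta_G_meta = mg$beta, se_G_meta = mg$se,
    chi2_joint = j$chi2, p_joint = j$p,
    joint_beta_G = j$beta[["beta_G"]], joint_beta_GL = j$beta[["beta_GL"]],
    joint_var_G = j$cov[1, 1], joint_var_GL = j$cov[2, 2],
    joint_cov = j$cov[1, 2],
    het_Q = het_Q, het_df = het_df, het_p = het_p,
    ancestry_group = ancestry_group,
    trait = g$trait[1], exposure = g$exposure[1],
    stringsAsFactors = FALSE
  )
}

#' Two-stage inverse-variance meta-analysis of cohort GLI statistics
#'
#' For each (variant, trait, exposure) group, cohorts are first combined
#' within each ancestry group; the ancestry-level estimates are then combined
#' into a trans-ancestry (`TRANS`) record using the same inverse-variance
#' scheme. The 1df interaction p-value is the two-sided normal test of
#' `beta_GL_meta / se_GL_meta`; the 2df joint statistic tests the genetic main
#' effect and the interaction together via the pooled precision matrix.
#' Heterogeneity (Cochran's Q on beta_GL) is computed over the direct inputs
#' of each combination and is undefined (NA) for single-input groups.
#'
#' @param cohort_stats data.frame of CohortGliStat rows (stacked
#'   [cohort_gli_stat()] output; columns per that function plus `ancestry`,
#'   `trait`, `exposure`).
#' @return data.frame of MetaGliRecord rows: one per ancestry group with >= 1
#'   cohort plus one TRANS record per (variant, trait, exposure).
#' @export
meta_analyze <- function(cohort_stats) {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "n", "beta_G", "se_G", "beta_GL", "se_GL", "cov_G_GL",
            "ancestry", "trait", "exposure")
  missing <- setdiff(need, names(cohort_stats))
  if (length(missing)) {
    stop_gliprio("invalid_params", "cohort_stats lacks columns: ",
                 paste(missing, collapse = ", "))
  }
  if (!nrow(cohort_stats)) {
    stop_gliprio("empty_input", "no cohort statistics supplied")
  }
  cohort_stats$k <- 1L
  key <- interaction(cohort_stats$variant_id, cohort_stats$trait,
                     cohort_stats$exposure, drop = TRUE)
  out <- lapply(split(cohort_stats, key), function(g) {
    anc <- lapply(split(g, g$ancestry, drop = TRUE), function(ga) {
      combine_group(ga, ancestry_group = ga$ancestry[1])
    })
    anc_df <- do.call(rbind, anc)
    # trans-ancestry stage consumes the ancestry-level estimates
    anc_in <- anc_df
    names(anc_in)[names(anc_in) == "pooled_eaf"] <- "eaf"
    names(anc_in)[names(anc_in) == "n_total"] <- "n"
    names(anc_in)[names(anc_in) == "beta_GL_meta"] <- "beta_GL"
    names(anc_in)[names(anc_in) == "se_GL_meta"] <- "se_GL"
    names(anc_in)[names(anc_in) == "beta_G_meta"] <- "beta_G"
    names(anc_in)[names(anc_in) == "se_G_meta"] <- "se_G"
    anc_in$k <- anc_df$k_cohorts
    trans <- combine_group(anc_in, ancestry_group = "TRANS")
    rbind(anc_df, trans)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$trait, out$exposure, out$variant_id, out$ancestry_group), ,
      drop = FALSE]
}

#' QC filter on meta-analyzed records
#'
#' Drops records with pooled minor allele frequency below `maf_min` (strict
#' `<`) or Cochran heterogeneity p below `het_alpha` (strict `<`). Records
#' from single-input combinations (heterogeneity undefined) skip the
#' heterogeneity filter.
#'
#' @param records MetaGliRecord data.frame from [meta_analyze()].
#' @param maf_min Minimum pooled MAF; default 0.01 (variants with MAF < 1%
#'   are excluded).
#' @param het_alpha Heterogeneity threshold; default 1e-6 (records with
#'   het p < 1e-6 are excluded).
#' @return List with `records` (retained rows) and `exclusions` (data.frame
#'   variant_id, ancestry_group, trait, exposure, reason).
#' @export
qc_filter <- function(records, maf_min = 0.01, het_alpha = 1e-6) {
  low_maf <- records$pooled_maf < maf_min
  het <- !is.na(records$het_p) & records$het_p < het_alpha
  reason <- ifelse(low_maf, "low MAF",
                   ifelse(het, "heterogeneity", NA_character_))
  drop <- low_maf | het
  exclusions <- data.frame(
    variant_id = records$variant_id[drop],
    ancestry_group = records$ancestry_group[drop],
    trait = records$trait[drop], exposure = records$exposure[drop],
    reason = reason[drop], stringsAsFactors = FALSE
  )
  list(records = records[!drop, , drop = FALSE], exclusions = exclusions)
}
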