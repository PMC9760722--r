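#' Parameters of the gene-by-lifestyle interaction model
#'
#' The generating model for one cohort is the standard GLI regression
#' \deqn{Y = \beta_0 + \beta_G G + \beta_C C + \beta_L L + \beta_{GL} G \times L + \epsilon,}
#' where G is an additive allele count (0/1/2), L a binary lifestyle exposure,
#' C a matrix of covariates and \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' @param beta0 Intercept, in trait units.
#' @param beta_G Per-allele main effect of the variant.
#' @param beta_L Main effect of the exposure.
#' @param beta_GL Interaction effect (the object of the whole pipeline).
#' @param beta_C Numeric vector of covariate effects (may be empty).
#' @param noise_sd Residual standard deviation; must be > 0.
#' @param eaf Effect-allele frequency, strictly in (0, 1).
#' @param exposure_prev Exposure prevalence, strictly in (0, 1).
#' @return An object of class `gli_params`.
#' @examples
#' gli_params(beta_GL = 0.15, eaf = 0.3, exposure_prev = 0.4)
#' @export
gli_params <- function(beta0 = 0, beta_G = 0, beta_L = 0, beta_GL = 0,
                       beta_C = numeric(0), noise_sd = 1,
                       eaf = 0.3, exposure_prev = 0.3) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_gliprio("invalid_params", "noise_sd must be a single positive number")
  }
  if (!is.numeric(eaf) || length(eaf) != 1L || eaf <= 0 || eaf >= 1) {
    stop_gliprio("invalid_params", "eaf must lie strictly in (0, 1)")
  }
  if (!is.numeric(exposure_prev) || length(exposure_prev) != 1L ||
      exposure_prev <= 0 || exposure_prev >= 1) {
    stop_gliprio("invalid_params", "exposure_prev must lie strictly in (0, 1)")
  }
  structure(list(beta0 = beta0, beta_G = beta_G, beta_L = beta_L,
                 beta_GL = beta_GL, beta_C = as.numeric(beta_C),
                 noise_sd = noise_sd, eaf = eaf,
                 exposure_prev = exposure_prev),
            class = "gli_params")
}

#' Specification of one contributing cohort
#'
#' @param cohort_id Cohort label.
#' @param n Sample size (at least 50).
#' @param ancestry One of the ancestry groups in [gli_ancestries()].
#' @param trait One of the traits in [gli_traits()].
#' @param exposure One of the exposures in [gli_exposures()].
#' @param seed Integer seed controlling this cohort's draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, n, ancestry, trait, exposure, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 50) {
    stop_gliprio("invalid_params", "cohort n must be at least 50")
  }
  if (!ancestry %in% gli_ancestries()) {
    stop_gliprio("vocabulary_violation", "unknown ancestry: ", ancestry)
  }
  if (!trait %in% gli_traits()) {
    stop_gliprio("vocabulary_violation", "unknown trait: ", trait)
  }
  if (!exposure %in% gli_exposures()) {
    stop_gliprio("vocabulary_violation", "unknown exposure: ", exposure)
  }
  structure(list(cohort_id = as.character(cohort_id), n = as.integer(n),
                 ancestry = ancestry, trait = trait, exposure = exposure,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate individual-level data for one cohort under the GLI model
#'
#' Genotypes are drawn binomial(2, eaf) (additive hard calls), the exposure is
#' Bernoulli with the given prevalence, covariates are independent standard
#' normals, and the phenotype is the linear predictor plus Gaussian noise.
#' Output is reproducible from `spec$seed`.
#'
#' @param params A [gli_params()] object.
#' @param spec A [cohort_spec()] object.
#' @param n_covariates Number of covariates to simulate; defaults to
#'   `length(params$beta_C)`.
#' @return A data.frame with columns `genotype`, `exposure`,
#'   `cov1..covK` (if any) and `phenotype`.
#' @examples
#' d <- simulate_cohort(gli_params(beta_GL = 0.5),
#'                      cohort_spec("c1", 500, "EA", "HDL", "ever smoking", 1))
#' head(d)
#' @export
simulate_cohort <- function(params, spec,
                            n_covariates = length(params$beta_C)) {
  stopifnot(inherits(params, "gli_params"), inherits(spec, "cohort_spec"))
  if (n_covariates < length(params$beta_C)) {
    stop_gliprio("invalid_params",
                 "n_covariates smaller than length(beta_C)")
  }
  beta_C <- c(params$beta_C, rep(0, n_covariates - length(params$beta_C)))
  n <- spec$n
  set.seed(spec$seed)
  G <- stats::rbinom(n, 2L, params$eaf)
  L <- stats::rbinom(n, 1L, params$exposure_prev)
  C <- if (n_covariates > 0) {
    matrix(stats::rnorm(n * n_covariates), nrow = n)
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  eta <- params$beta0 + params$beta_G * G + params$beta_L * L +
    params$beta_GL * G * L +
    if (n_covariates > 0) drop(C %*% beta_C) else 0
  Y <- eta + stats::rnorm(n, 0, params$noise_sd)
  out <- data.frame(genotype = G, exposure = L)
  if (n_covariates > 0) {
    colnames(C) <- paste0("cov", seq_len(n_covariates))
    out <- cbind(out, as.data.frame(C))
  }
  out$phenotype <- Y
  out
}

#' Fit the GLI model to individual-level cohort data
#'
#' Ordinary least squares of the phenotype on genotype, exposure, their
#' product and any covariates, with model-based standard errors. The pieces a
#' summary-statistics meta-analysis needs — the genetic main effect, the
#' interaction effect, their standard errors and their estimated covariance —
#' are extracted from the fit.
#'
#' @param data A data.frame as returned by [simulate_cohort()]: columns
#'   `genotype`, `exposure`, `phenotype` and optionally `cov*`.
#' @return An object of class `gli_fit` with components `beta_G`, `se_G`,
#'   `beta_GL`, `se_GL`, `cov_G_GL`, `p_G`, `p_int` (two-sided t-tests),
#'   `df_residual`, `eaf` (in-sample effect-allele frequency), `n`, and the
#'   underlying `lm` fit.
#' @examples
#' d <- simulate_cohort(gli_params(beta_GL = 0.5, noise_sd = 0.5),
#'                      cohort_spec("c1", 2000, "EA", "HDL", "ever smoking", 1))
#' fit <- fit_gli(d)
#' coef(fit)
#' summary(fit)
#' @export
fit_gli <- function(data) {
  need <- c("genotype", "exposure", "phenotype")
  if (!all(need %in% names(data))) {
    stop_gliprio("invalid_params", "data must have columns ",
                 paste(need, collapse = ", "))
  }
  if (stats::var(data$genotype) == 0 || stats::var(data$exposure) == 0 ||
      stats::var(data$genotype * data$exposure) == 0) {
    stop_gliprio("degenerate_design",
                 "genotype, exposure and their product must all vary")
  }
  covs <- grep("^cov", names(data), value = TRUE)
  rhs <- paste(c("genotype * exposure", covs), collapse = " + ")
  n_par <- 4L + length(covs)
  if (nrow(data) < n_par + 10L) {
    stop_gliprio("invalid_params",
                 "need at least 10 more rows than model parameters")
  }
  fit <- stats::lm(stats::as.formula(paste("phenotype ~", rhs)), data = data)
  V <- stats::vcov(fit)
  cf <- stats::coef(fit)
  sm <- stats::coef(summary(fit))
  ia <- "genotype:exposure"
  if (anyNA(cf[c("genotype", ia)])) {
    stop_gliprio("degenerate_design", "collinear design: coefficients dropped")
  }
  structure(list(
    beta_G = unname(cf["genotype"]),
    se_G = unname(sqrt(V["genotype", "genotype"])),
    beta_GL = unname(cf[ia]),
    se_GL = unname(sqrt(V[ia, ia])),
    cov_G_GL = unname(V["genotype", ia]),
    p_G = unname(sm["genotype", "Pr(>|t|)"]),
    p_int = unname(sm[ia, "Pr(>|t|)"]),
    df_residual = fit$df.residual,
    eaf = mean(data$genotype) / 2,
    n = nrow(data),
    lm_fit = fit
  ), class = "gli_fit")
}

#' @export
print.gli_fit <- function(x, ...) {
  cat("Gene-by-lifestyle interaction fit (OLS)\n")
  cat(sprintf("  n = %d, residual df = %d, EAF = %.4f\n",
              x$n, x$df_residual, x$eaf))
  cat(sprintf("  beta_G  = %9.5f (se %.5f)\n", x$beta_G, x$se_G))
  cat(sprintf("  beta_GL = %9.5f (se %.5f), interaction p = %.3g\n",
              x$beta_GL, x$se_GL, x$p_int))
  invisible(x)
}

#' @export
coef.gli_fit <- function(object, ...) {
  c(beta_G = object$beta_G, beta_GL = object$beta_GL)
}

#' @export
vcov.gli_fit <- function(object, ...) {
  matrix(c(object$se_G^2, object$cov_G_GL,
           object$cov_G_GL, object$se_GL^2), 2, 2,
         dimnames = list(c("beta_G", "beta_GL"), c("beta_G", "beta_GL")))
}

#' @export
confint.gli_fit <- function(object, parm = c("beta_G", "beta_GL"),
                            level = 0.95, ...) {
  est <- coef(object)[parm]
  se <- sqrt(diag(vcov(object)))[parm]
  q <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  out <- cbind(est - q * se, est + q * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  out
}

#' @export
summary.gli_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm_fit)),
            class = "summary.gli_fit")
}

#' @export
print.summary.gli_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFull regression table:\n")
  stats::printCoefmat(stats::coef(x$lm_summary))
  invisible(x)
}

#' Package a cohort fit as a summary-statistics record
#'
#' Produces the one-row METAL-style record a cohort contributes to the
#' meta-analysis: variant identity and alleles, in-sample effect-allele
#' frequency, sample size, and the estimated (beta_G, beta_GL) with standard
#' errors and covariance.
#'
#' @param fit A [fit_gli()] object.
#' @param spec The [cohort_spec()] the data came from.
#' @param variant_id,chrom,pos,effect_allele,other_allele Variant identity.
#' @return A one-row data.frame (a CohortGliStat record).
#' @export
cohort_gli_stat <- function(fit, spec, variant_id, chrom, pos,
                            effect_allele, other_allele) {
  stopifnot(inherits(fit, "gli_fit"), inherits(spec, "cohort_spec"))
  data.frame(
    variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = fit$eaf, n = fit$n,
    beta_G = fit$beta_G, se_G = fit$se_G,
    beta_GL = fit$beta_GL, se_GL = fit$se_GL, cov_G_GL = fit$cov_G_GL,
    p_int = fit$p_int,
    ancestry = spec$ancestry, trait = spec$trait, exposure = spec$exposure,
    cohort_id = spec$cohort_id,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort and return its summary-statistics record
#'
#' Convenience wrapper: [simulate_cohort()] then [fit_gli()] then
#' [cohort_gli_stat()].
#'
#' @inheritParams simulate_cohort
#' @inheritParams cohort_gli_stat
#' @return A one-row CohortGliStat data.frame.
#' @export
simulate_cohort_stats <- function(params, spec, variant_id = "rs1",
                                  chrom = "chr1", pos = 1000000L,
                                  effect_allele = "A", other_allele = "G",
                                  n_covariates = length(params$beta_C)) {
  d <- simulate_cohort(params, spec, n_covariates)
  cohort_gli_stat(fit_gli(d), spec, variant_id, chrom, pos,
                  effect_allele, other_allele)
}
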