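make_stat <- function(variant_id = "rs1", beta_G = 0.1, se_G = 0.05,
                      beta_GL = 0.2, se_GL = 0.1, cov_G_GL = 0.001,
                      eaf = 0.3, n = 1000, ancestry = "EA",
                      effect_allele = "A", other_allele = "G",
                      trait = "HDL", exposure = "ever smoking",
                      cohort_id = "c1", chrom = "chr1", pos = 100L) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, n = n, beta_G = beta_G, se_G = se_G,
             beta_GL = beta_GL, se_GL = se_GL, cov_G_GL = cov_G_GL,
             p_int = NA_real_, ancestry = ancestry, trait = trait,
             exposure = exposure, cohort_id = cohort_id,
             stringsAsFactors = FALSE)
}

test_that("allele alignment flips, passes through, or signals mismatch", {
  s <- make_stat(beta_G = 0.1, beta_GL = 0.2, eaf = 0.3, cov_G_GL = 0.002)
  same <- align_alleles(s, c("A", "G"))
  expect_equal(same$beta_GL, 0.2)
  expect_equal(same$eaf, 0.3)
  expect_false(same$strand_ambiguous)

  sw <- make_stat(effect_allele = "G", other_allele = "A",
                  beta_G = 0.1, beta_GL = 0.2, eaf = 0.3, cov_G_GL = 0.002)
  fl <- align_alleles(sw, c("A", "G"))
  expect_equal(fl$beta_GL, -0.2)
  expect_equal(fl$beta_G, -0.1)
  expect_equal(fl$eaf, 0.7)
  expect_equal(fl$cov_G_GL, 0.002)  # both signs flip, covariance unchanged
  expect_identical(fl$effect_allele, "A")

  amb <- align_alleles(make_stat(effect_allele = "A", other_allele = "T"),
                       c("A", "T"))
  expect_true(amb$strand_ambiguous)

  expect_error(align_alleles(make_stat(effect_allele = "A",
                                       other_allele = "C"), c("A", "G")),
               class = "gliprio_allele_mismatch")
})

test_that("inverse-variance meta matches hand arithmetic", {
  expect_equal(inverse_variance_meta(0.1, 0.05), list(beta = 0.1, se = 0.05))
  m <- inverse_variance_meta(c(0.1, 0.2), c(0.05, 0.1))
  expect_equal(m$beta, 0.12)                 # w = 400, 100
  expect_equal(m$se, sqrt(1 / 500))          # ~0.044721
  sym <- inverse_variance_meta(c(0.3, -0.3), c(0.07, 0.07))
  expect_equal(sym$beta, 0)
  expect_error(inverse_variance_meta(numeric(0), numeric(0)),
               class = "gliprio_empty_input")
  expect_error(inverse_variance_meta(0.1, 0), class = "gliprio_invalid_params")
})

test_that("Cochran's Q matches hand arithmetic and is scale-invariant", {
  q0 <- cochran_q(c(0.2, 0.2, 0.2), c(0.05, 0.1, 0.2))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)
  q <- cochran_q(c(0.1, 0.2), c(0.05, 0.1), beta_meta = 0.12)
  expect_equal(q$Q, 400 * 0.0004 + 100 * 0.0064)  # = 0.8
  expect_identical(q$df, 1L)
  set.seed(31)
  b <- rnorm(5); s <- runif(5, 0.05, 0.2)
  expect_equal(cochran_q(3 * b, 3 * s)$Q, cochran_q(b, s)$Q)
  # brute-force recomputation on random instances
  for (i in 1:10) {
    b <- rnorm(4); s <- runif(4, 0.05, 0.3)
    bm <- sum(b / s^2) / sum(1 / s^2)
    expect_equal(cochran_q(b, s)$Q, sum((b - bm)^2 / s^2))
  }
  expect_error(cochran_q(0.1, 0.05), class = "gliprio_insufficient_cohorts")
})

test_that("2df joint meta matches quadratic-form oracles", {
  z0 <- joint_2df_meta(0, 0, 0.05, 0.1, 0)
  expect_equal(z0$chi2, 0)
  expect_equal(z0$p, 1)
  # diagonal single cohort with both estimates at 2 SEs: chi2 = 4 + 4
  j <- joint_2df_meta(0.1, 0.2, 0.05, 0.1, 0)
  expect_equal(j$chi2, 8)
  # two identical cohorts halve the pooled covariance
  j1 <- joint_2df_meta(0.1, 0.2, 0.05, 0.1, 0.002)
  j2 <- joint_2df_meta(c(0.1, 0.1), c(0.2, 0.2), c(0.05, 0.05),
                       c(0.1, 0.1), c(0.002, 0.002))
  expect_equal(j2$cov, j1$cov / 2)
  expect_equal(unname(j2$beta), unname(j1$beta))
  expect_error(joint_2df_meta(0.1, 0.2, 0.05, 0.1, 0.05^2 * 2),
               class = "gliprio_singular_precision")
})

test_that("meta-analysis is two-stage and contracts standard errors", {
  stats <- rbind(
    make_stat(cohort_id = "c1", ancestry = "EA", beta_GL = 0.15, se_GL = 0.08,
              beta_G = 0.05, se_G = 0.04, eaf = 0.3, n = 1000),
    make_stat(cohort_id = "c2", ancestry = "EA", beta_GL = 0.25, se_GL = 0.10,
              beta_G = 0.02, se_G = 0.05, eaf = 0.35, n = 1500),
    make_stat(cohort_id = "c3", ancestry = "AA", beta_GL = 0.10, se_GL = 0.12,
              beta_G = 0.08, se_G = 0.06, eaf = 0.25, n = 800)
  )
  rec <- meta_analyze(stats)
  trans <- rec[rec$ancestry_group == "TRANS", ]
  ea <- rec[rec$ancestry_group == "EA", ]
  aa <- rec[rec$ancestry_group == "AA", ]
  expect_identical(nrow(rec), 3L)
  # two-stage equals one-stage for se-based weights
  direct <- inverse_variance_meta(stats$beta_GL, stats$se_GL)
  expect_equal(trans$beta_GL_meta, direct$beta, tolerance = 1e-10)
  expect_equal(trans$se_GL_meta, direct$se, tolerance = 1e-10)
  # trans equals direct meta of the two ancestry-level estimates
  two <- inverse_variance_meta(c(ea$beta_GL_meta, aa$beta_GL_meta),
                               c(ea$se_GL_meta, aa$se_GL_meta))
  expect_equal(trans$beta_GL_meta, two$beta, tolerance = 1e-12)
  # joint 2df pools precision matrices associatively too
  jd <- joint_2df_meta(stats$beta_G, stats$beta_GL, stats$se_G, stats$se_GL,
                       stats$cov_G_GL)
  expect_equal(trans$chi2_joint, jd$chi2, tolerance = 1e-10)
  # fixed-effect contraction and convex hull
  expect_lt(ea$se_GL_meta, min(0.08, 0.10))
  expect_gte(ea$beta_GL_meta, 0.15)
  expect_lte(ea$beta_GL_meta, 0.25)
  # pooled EAF is N-weighted
  expect_equal(ea$pooled_eaf, (0.3 * 1000 + 0.35 * 1500) / 2500)
  # single-ancestry group: TRANS record equals the ancestry record
  one <- meta_analyze(stats[stats$ancestry == "AA", ])
  expect_equal(one$beta_GL_meta[one$ancestry_group == "TRANS"],
               one$beta_GL_meta[one$ancestry_group == "AA"])
  expect_equal(one$se_GL_meta[one$ancestry_group == "TRANS"],
               one$se_GL_meta[one$ancestry_group == "AA"])
})

test_that("two-stage equivalence holds on random instances", {
  set.seed(77)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    stats <- do.call(rbind, lapply(seq_len(k), function(j) {
      make_stat(cohort_id = paste0("c", j),
                ancestry = sample(gli_ancestries(), 1),
                beta_G = rnorm(1, 0, 0.1), se_G = runif(1, 0.02, 0.1),
                beta_GL = rnorm(1, 0, 0.2), se_GL = runif(1, 0.05, 0.2),
                cov_G_GL = runif(1, -5e-4, 5e-4),
                eaf = runif(1, 0.05, 0.95), n = sample(500:5000, 1))
    }))
    rec <- meta_analyze(stats)
    trans <- rec[rec$ancestry_group == "TRANS", ]
    direct <- inverse_variance_meta(stats$beta_GL, stats$se_GL)
    expect_equal(trans$beta_GL_meta, direct$beta, tolerance = 1e-10)
    expect_equal(trans$se_GL_meta, direct$se, tolerance = 1e-10)
  }
})

test_that("1df p from the joint machinery with main effect removed equals the scalar test", {
  set.seed(12)
  b <- rnorm(4, 0, 0.2); s <- runif(4, 0.05, 0.2)
  # main-effect row removed: beta_G = 0 with cov 0 contributes nothing to the
  # interaction component, so chi2 reduces to (beta_GL_meta / se_GL_meta)^2
  j <- joint_2df_meta(rep(0, 4), b, rep(1, 4), s, rep(0, 4))
  m <- inverse_variance_meta(b, s)
  expect_equal(j$chi2, (m$beta / m$se)^2, tolerance = 1e-12)
  p_1df <- 2 * pnorm(-abs(m$beta / m$se))
  expect_equal(pchisq((m$beta / m$se)^2, 1, lower.tail = FALSE), p_1df,
               tolerance = 1e-12)
})

test_that("QC filter applies strict MAF and heterogeneity thresholds", {
  rec <- meta_analyze(rbind(
    make_stat(cohort_id = "c1", beta_GL = 0.1, se_GL = 0.05),
    make_stat(cohort_id = "c2", beta_GL = 0.12, se_GL = 0.05)))
  ea <- rec[rec$ancestry_group == "EA", ]

  low <- ea; low$pooled_maf <- 0.005
  out <- qc_filter(low)
  expect_identical(nrow(out$records), 0L)
  expect_identical(out$exclusions$reason, "low MAF")

  exact <- ea; exact$pooled_maf <- 0.01
  expect_identical(nrow(qc_filter(exact)$records), 1L)

  het <- ea; het$het_p <- 1e-7
  out2 <- qc_filter(het)
  expect_identical(out2$exclusions$reason, "heterogeneity")

  het_edge <- ea; het_edge$het_p <- 1e-6
  expect_identical(nrow(qc_filter(het_edge)$records), 1L)

  # single-cohort records (undefined het) skip the heterogeneity filter
  single <- ea; single$het_p <- NA_real_
  expect_identical(nrow(qc_filter(single)$records), 1L)
})
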