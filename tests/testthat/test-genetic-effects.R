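# The core contribution: per-allele multiplicative effects on the biomarker,
# genotype effects normalized to population mean 1, multiplicative combination
# across SNPs, and division of the measured biomarker.

test_that("normalized genotype effects: direct evaluation, neutrality, structure", {
  # direct evaluation against the defining formula, written out independently
  p <- 0.33; a <- 1.08
  E <- (1 - p)^2 + 2 * p * (1 - p) * a + p^2 * a^2
  e <- genotype_effects(p, a)
  expect_equal(as.numeric(e), c(1, a, a^2) / E, tolerance = 1e-15)
  expect_equal(attr(e, "mean_effect"), E)

  # the second panel SNP under the same normalization (frequency 0.47,
  # allelic effect 1.10) -- evaluates to 0.91 / 1.00 / 1.10 at 2 decimals
  e2 <- genotype_effects(0.47, 1.10)
  expect_equal(as.numeric(round(e2, 2)), c(0.91, 1.00, 1.10))

  # neutral allele
  expect_equal(as.numeric(genotype_effects(0.5, 1)), c(1, 1, 1))

  # multiplicative-ratio and mean-1 invariants over random (p, a)
  set.seed(17)
  for (i in 1:50) {
    pp <- runif(1, 0.01, 0.99)
    aa <- exp(runif(1, log(0.5), log(2)))  # decreasing alleles allowed
    ee <- genotype_effects(pp, aa)
    expect_equal(ee[["e_OX"]] / ee[["e_OO"]], aa, tolerance = 1e-12)
    expect_equal(ee[["e_XX"]] / ee[["e_OO"]], aa^2, tolerance = 1e-12)
    w <- c((1 - pp)^2, 2 * pp * (1 - pp), pp^2)
    expect_equal(sum(w * ee), 1, tolerance = 1e-9)
  }

  # empirical weights: mean-1 holds under the observed genotype proportions
  cnt <- c(400, 460, 140)
  ee <- genotype_effects(a = 1.2, weights = "empirical", counts = cnt)
  expect_equal(sum(cnt / sum(cnt) * ee), 1, tolerance = 1e-12)

  expect_error(genotype_effects(1.5, 1.08), "p")
  expect_error(genotype_effects(0.3, -1), "a")
  expect_error(genotype_effects(a = 1.1, weights = "empirical",
                                counts = c(-1, 2, 3)), "counts")
})

test_that("snp_effect validates the multiplicative invariants", {
  se <- snp_effect("rs12506899", p = 0.33, a = 1.08, chrom = "4",
                   pos_bp = 74538147L, effect_allele = "T")
  expect_s3_class(se, "snp_effect")
  expect_equal(se$e_OX / se$e_OO, 1.08, tolerance = 1e-12)

  # inconsistent hand-supplied effects are rejected
  expect_error(snp_effect("rsBad", p = 0.3, a = 1.5,
                          effects = c(1.0, 1.1, 1.2)),
               "multiplicative")

  # published values rounded to 2 dp are accepted at the looser tolerance
  expect_s3_class(snp_effect("rs12506899", p = 0.33, a = 1.08,
                             effects = c(0.95, 1.02, 1.10)),
                  "snp_effect")
})

test_that("allelic-effect estimation: exact fit, null, and recovery from simulation", {
  # perfectly noiseless log-linear data -> exact back-transformed slope
  d <- rep(0:2, each = 30)
  y <- exp(d * log(1.1))
  # lm flags the zero-residual fit as "essentially perfect"; that is the point
  fit <- suppressWarnings(fit_allelic_effect(d, y))
  expect_equal(fit$a_hat, 1.1, tolerance = 1e-12)

  # null: biomarker independent of dosage
  set.seed(4)
  d <- rbinom(20000, 2, 0.33)
  y <- exp(rnorm(20000, 1, 1))
  f0 <- fit_allelic_effect(d, y)
  expect_lt(abs(f0$log_a_hat), 3 * f0$se_log)

  # recovery at cohort scale with the default panel effect
  panel <- afp_snp_panel()[1, ]
  dos <- simulate_genotypes(50000, panel, seed = 6)
  afp <- simulate_afp(dos, panel, afp_median = 2.7, log_noise_sd = 1,
                      detection_limit = 0.005, seed = 7)
  f <- fit_allelic_effect(dos[, 1], afp$observed)
  expect_lt(abs(f$log_a_hat - log(1.08)), 3 * f$se_log)
  expect_equal(f$n_used, 50000)

  expect_error(fit_allelic_effect(rep(1L, 100), runif(100, 1, 2)),
               "monomorphic")
  expect_error(fit_allelic_effect(c(0, 1, 2), c(1, -2, 3)),
               "detection-limit")
})

test_that("combined genetic factor: products, neutral imputation, correction identity", {
  effs <- list(snp_effect("rs12506899", p = 0.33, a = 1.08),
               snp_effect("rs2251844", p = 0.47, a = 1.10))

  # dosages (0, 2): product of the exact unrounded per-genotype factors
  G <- combine_effects(effs, c(rs12506899 = 0L, rs2251844 = 2L))
  expect_equal(as.numeric(G), effs[[1]]$e_OO * effs[[2]]$e_XX,
               tolerance = 1e-15)
  expect_equal(attr(G, "n_snps_used"), 2L)

  # all genotypes missing: neutral factor with flags, participant retained
  Gm <- combine_effects(effs, c(NA_integer_, NA_integer_))
  expect_equal(as.numeric(Gm), 1)
  expect_length(attr(Gm, "flags"), 2)

  # single-SNP panel: the product is just that genotype's effect
  G1 <- combine_effects(effs[1], 1L)
  expect_equal(as.numeric(G1), effs[[1]]$e_OX)

  expect_error(combine_effects(effs, c(0L, 3L)), "rs2251844")

  # corrected x G returns the measurement exactly; G = 1 is the identity
  afp <- c(7.85, 0.005, 123.4)
  G <- c(1.0535, 0.91, 1.2)
  expect_identical(correct_biomarker(afp, rep(1, 3)), afp)
  expect_equal(correct_biomarker(afp, G) * G, afp, tolerance = 1e-15)
  # published before/after pair as an arithmetic identity
  expect_equal(correct_biomarker(7.85, 7.85 / 7.17), 7.17, tolerance = 1e-12)
  expect_error(correct_biomarker(7.85, 0), "G")
  expect_error(correct_biomarker(-1, 1), "biomarker")
})

test_that("cohort correction removes the genotype signal and summarizes change", {
  cfg <- sim_config(n_participants = 20000)
  coh <- simulate_cohort(cfg, seed = 12)
  corr <- cohort_correction(coh, afp_snp_panel(), weights = "hwe")

  # per-row inverse identity
  expect_equal(corr$result$corrected * corr$result$G, coh$afp_ng_ml,
               tolerance = 1e-12)

  # signal removal: log corrected AFP no longer associates with dosage
  for (s in afp_snp_panel()$snp_id) {
    fit <- stats::lm(log(corr$result$corrected) ~ coh[[s]])
    slope <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(slope), 3 * se)
  }

  # no renormalization of the multi-SNP product is needed: mean(G) ~ 1
  expect_lt(abs(mean(corr$result$G) - 1),
            3 * stats::sd(corr$result$G) / sqrt(nrow(coh)))

  # summary arithmetic, including the published-means example
  expect_equal(pct_reduction(7.85, 7.17), 8.7)
  expect_equal(pct_reduction(5, 5), 0)

  # scale equivariance: rescaling the biomarker rescales corrected values,
  # leaves G untouched
  coh_k <- coh
  coh_k$afp_ng_ml <- coh_k$afp_ng_ml * 3
  corr_k <- cohort_correction(coh_k, afp_snp_panel())
  expect_equal(corr_k$result$G, corr$result$G)
  expect_equal(corr_k$result$corrected, 3 * corr$result$corrected,
               tolerance = 1e-12)

  # missing panel column is named
  expect_error(cohort_correction(coh[, setdiff(names(coh), "rs2251844")]),
               "rs2251844")

  # missing genotypes: retained with neutral factors and flags
  cohm <- simulate_cohort(sim_config(n_participants = 2000,
                                     missing_rate = 0.2), seed = 13)
  corrm <- cohort_correction(cohm)
  expect_equal(nrow(corrm$result), 2000)
  expect_true(any(corrm$result$flagged))
  i <- which(is.na(cohm$rs12506899) & is.na(cohm$rs2251844))[1]
  expect_equal(corrm$result$G[i], 1)

  # empirical weights mode runs and keeps mean(G) ~ 1 under observed counts
  corr_emp <- cohort_correction(coh, afp_snp_panel(), weights = "empirical")
  expect_lt(abs(mean(corr_emp$result$G) - 1), 0.01)
})

test_that("allelic effects are recovered across seeds at cohort scale", {
  # 20-seed spot check of the estimator's accuracy under study conditions
  # (the full 100-seed sweep runs with the acceptance properties)
  panel <- afp_snp_panel()
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    dos <- simulate_genotypes(50000, panel, seed = 1000 + s)
    afp <- simulate_afp(dos, panel, 2.7, 1.0, 0.005, seed = 2000 + s)
    for (k in 1:2) {
      f <- fit_allelic_effect(dos[, k], afp$observed)
      hits <- hits + (abs(f$a_hat - panel$allelic_effect[k]) <= 0.02)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
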