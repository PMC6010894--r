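# The generator must reproduce the statistical structure the correction
# assumes: HWE genotypes, log-linear genotype effects on the biomarker,
# a detection-limit floor, a rare outcome with a solved marginal incidence,
# and configured covariate marginals -- all bit-reproducible under a seed.

test_that("genotype simulation follows HWE and is seed-deterministic", {
  panel <- afp_snp_panel()

  d1 <- simulate_genotypes(5000, panel, seed = 11)
  d2 <- simulate_genotypes(5000, panel, seed = 11)
  expect_identical(d1, d2)
  expect_identical(colnames(d1), panel$snp_id)

  # degenerate frequency
  p0 <- panel; p0$allele_freq[1] <- 0
  expect_true(all(simulate_genotypes(200, p0, seed = 1)[, 1] == 0L))

  # allele frequency and genotype proportions at n = 100k
  n <- 100000
  d <- simulate_genotypes(n, panel, seed = 42)
  for (k in 1:2) {
    p <- panel$allele_freq[k]
    se <- sqrt(p * (1 - p) / (2 * n))
    expect_lt(abs(mean(d[, k]) / 2 - p), 3 * se)
    obs <- tabulate(d[, k] + 1L, nbins = 3)
    expt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((obs - expt)^2 / expt)
    expect_gt(stats::pchisq(chi2, df = 2, lower.tail = FALSE), 0.001)
  }

  expect_error(simulate_genotypes(100, data.frame(snp_id = "rsX",
                                                  allele_freq = 1.2,
                                                  allelic_effect = 1)),
               "rsX")
})

test_that("AFP model: neutral limit, slope recovery and exact detection floor", {
  panel <- afp_snp_panel()
  n <- 20000
  dos <- simulate_genotypes(n, panel, seed = 5)

  # neutral panel, vanishing noise -> every latent value equals the median
  afp0 <- simulate_afp(dos, neutral_panel(), afp_median = 2.7,
                       log_noise_sd = 1e-12, detection_limit = 0.005, seed = 1)
  expect_equal(afp0$latent, rep(2.7, n), tolerance = 1e-9)

  # with real effects, OLS of log observed AFP on dosage recovers log(a_s)
  # (floor made non-binding so the regression is on the clean generative model)
  afp <- simulate_afp(dos, panel, afp_median = 2.7, log_noise_sd = 1,
                      detection_limit = 1e-12, seed = 2)
  for (k in 1:2) {
    fit <- stats::lm(log(afp$observed) ~ dos[, k])
    slope <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(slope - log(panel$allelic_effect[k])), 3 * se)
  }

  # decomposition: latent = genotype-free signal x combined genetic factor
  expect_equal(afp$latent, afp$signal * afp$genetic_factor, tolerance = 1e-12)

  # the floor clamps exactly to the configured detection limit
  low <- simulate_afp(dos[1:2000, ], panel, afp_median = 0.02,
                      log_noise_sd = 2, detection_limit = 0.005, seed = 3)
  below <- low$latent < 0.005
  expect_gt(sum(below), 0)
  expect_true(all(low$observed[below] == 0.005))
  expect_true(all(low$observed >= 0.005))

  expect_error(simulate_afp(dos, panel, afp_median = -1), "afp_median")
})

test_that("outcome model: solved intercept, null effect, target case counts", {
  withr_seed <- 99
  set.seed(withr_seed)
  x <- exp(rnorm(100000, log(2.7), 1))

  # the intercept reproduces the requested marginal to within 1e-6
  beta <- log(5)
  alpha <- solve_logistic_intercept(x, beta, 0.00581)
  expect_lt(abs(mean(stats::plogis(alpha + beta * x / 10)) - 0.00581), 1e-6)

  # OR = 1: outcome independent of AFP, incidence at the configured level
  y0 <- simulate_outcome(x, true_or_per_10 = 1, baseline_incidence = 0.1,
                         seed = 1)
  se <- sqrt(0.1 * 0.9 / length(x))
  expect_lt(abs(mean(y0) - 0.1), 3 * se)
  expect_lt(abs(stats::cor(x, y0)), 0.01)

  # study conditions: ~581 cases expected out of 100k at 5.81 per 1000
  y <- simulate_outcome(x, true_or_per_10 = 5, baseline_incidence = 0.00581,
                        seed = 2)
  se_cases <- sqrt(100000 * 0.00581 * (1 - 0.00581))
  expect_lt(abs(sum(y) - 581), 3 * se_cases)

  expect_error(simulate_outcome(x, true_or_per_10 = 5,
                                baseline_incidence = 1e-30),
               "unattainable")
})

test_that("covariate marginals match the configured prevalences and moments", {
  n <- 100000
  cov <- simulate_covariates(n, seed = 8)
  expect_setequal(names(cov), names(default_covariate_spec()))

  se_smoke <- sqrt(0.303 * 0.697 / n)
  expect_lt(abs(mean(cov$smoking) - 0.303), 3 * se_smoke)

  expect_lt(abs(mean(cov$age) - 62.09), 3 * 7.78 / sqrt(n))
  expect_lt(abs(stats::sd(cov$age) - 7.78), 3 * 7.78 / sqrt(2 * n))

  spec <- default_covariate_spec()
  spec$smoking$prevalence <- 0
  expect_true(all(simulate_covariates(500, spec, seed = 1)$smoking == 0))

  spec$weird <- list(type = "categorical", prevalence = 0.5)
  expect_error(sim_config(covariates = spec), "weird")
})

test_that("cohort TSV round-trips losslessly and the reader enforces the contract", {
  coh <- simulate_cohort(quick_config(n = 300,
                                      missing_rate = 0.05), seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as_plain(back), as_plain(coh), tolerance = 1e-12)
  expect_true(anyNA(back$rs12506899))  # missingness survives the round trip

  # corrupt one dosage -> rejected with the row number and SNP
  lines <- readLines(path)
  bad <- strsplit(lines[4], "\t")[[1]]
  bad[length(bad)] <- "3"
  lines[4] <- paste(bad, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_cohort(path), "row 3")

  # AFP below the floor is accepted but reported
  coh2 <- coh
  coh2$afp_ng_ml[1] <- 0.001
  write_cohort(coh2, path)
  expect_message(read_cohort(path), "below the detection limit")

  # non-positive AFP rejected
  coh2$afp_ng_ml[2] <- -1
  write_cohort(coh2, path)
  expect_error(read_cohort(path), "non-positive AFP at row 2")
})

test_that("full cohort generation is deterministic and neutral alleles give a null", {
  cfg <- quick_config(n = 1500)
  c1 <- simulate_cohort(cfg, seed = 33)
  c2 <- simulate_cohort(cfg, seed = 33)
  expect_identical(as_plain(c1), as_plain(c2))
  expect_false(identical(c1$afp_ng_ml, simulate_cohort(cfg, seed = 34)$afp_ng_ml))
  expect_false(anyDuplicated(c1$id) > 0)

  # null panel: the downstream correction must leave AFP unchanged
  cfg0 <- quick_config(n = 1500, snp_panel = neutral_panel())
  c0 <- simulate_cohort(cfg0, seed = 33)
  corr <- cohort_correction(c0, neutral_panel())
  expect_equal(corr$result$corrected, c0$afp_ng_ml, tolerance = 1e-12)
  expect_equal(corr$relative_change_pct, 0, tolerance = 1e-9)
})
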