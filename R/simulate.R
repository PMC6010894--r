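# Synthetic cohorts with the statistical structure the correction assumes:
# HWE genotypes, log-normal biomarker with per-allele multiplicative effects,
# a rare binary outcome driven by the genotype-free biomarker component, and
# independent baseline covariates matching the cohort's published marginals.

#' Default covariate specification
#'
#' Marginal distributions of the baseline covariates of the study population:
#' binary covariates by prevalence, age and BMI as normal mean/SD. `sex` codes
#' male = 1 (prevalence is the male fraction).
#'
#' @return named list; each element is `list(type = "binary", prevalence = p)`
#'   or `list(type = "normal", mean = m, sd = s)`.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(type = "normal", mean = 62.09, sd = 7.78),
    sex = list(type = "binary", prevalence = 0.469),
    bmi = list(type = "normal", mean = 24.33, sd = 3.32),
    smoking = list(type = "binary", prevalence = 0.303),
    drinking = list(type = "binary", prevalence = 0.272),
    marriage = list(type = "binary", prevalence = 0.899),
    education = list(type = "binary", prevalence = 0.104),
    physical_activity = list(type = "binary", prevalence = 0.885),
    family_history = list(type = "binary", prevalence = 0.030)
  )
}

#' Simulation configuration
#'
#' Collects and validates everything the cohort generator needs. Defaults are
#' the study conditions: n = 9819 participants, the two-SNP AFP panel, AFP
#' median 2.70 ng/mL with detection-limit floor 0.005 ng/mL, log-scale residual
#' SD 1.0, marginal HCC incidence 5.81 per 1000, and a true odds ratio of 5.0
#' per 10 ng/mL of the genotype-free AFP component.
#'
#' @param n_participants cohort size.
#' @param snp_panel data.frame as [afp_snp_panel()].
#' @param log_noise_sd SD of the natural-log AFP residual.
#' @param afp_median population median AFP, ng/mL.
#' @param detection_limit assay floor, ng/mL; observed values below it are set
#'   to it exactly.
#' @param baseline_incidence marginal outcome probability.
#' @param true_or_per_10 generative odds ratio per 10 ng/mL of the
#'   genotype-free AFP component.
#' @param covariates covariate spec as [default_covariate_spec()].
#' @param missing_rate per-genotype missingness probability (default 0).
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 9819,
                       snp_panel = afp_snp_panel(),
                       log_noise_sd = 1.0,
                       afp_median = 2.70,
                       detection_limit = 0.005,
                       baseline_incidence = 0.00581,
                       true_or_per_10 = 5.0,
                       covariates = default_covariate_spec(),
                       missing_rate = 0) {
  check_number(n_participants, "n_participants", lower = 1)
  check_panel(snp_panel)
  if (any(snp_panel$allele_freq <= 0 | snp_panel$allele_freq >= 1))
    stop_("sim_config requires panel allele frequencies strictly inside (0,1)")
  check_number(log_noise_sd, "log_noise_sd", lower = 0, strict_lower = TRUE)
  check_number(afp_median, "afp_median", lower = 0, strict_lower = TRUE)
  check_number(detection_limit, "detection_limit", lower = 0, strict_lower = TRUE)
  check_prob(baseline_incidence, "baseline_incidence")
  check_number(true_or_per_10, "true_or_per_10", lower = 0, strict_lower = TRUE)
  check_prob(missing_rate, "missing_rate", open = FALSE)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!cv$type %in% c("binary", "normal"))
      stop_(sprintf("covariate %s has unknown type %s", nm, cv$type))
    if (cv$type == "binary") check_prob(cv$prevalence, nm, open = FALSE)
    else check_number(cv$sd, paste0(nm, "$sd"), lower = 0, strict_lower = TRUE)
  }
  structure(
    list(n_participants = as.integer(n_participants), snp_panel = snp_panel,
         log_noise_sd = log_noise_sd, afp_median = afp_median,
         detection_limit = detection_limit,
         baseline_incidence = baseline_incidence,
         true_or_per_10 = true_or_per_10, covariates = covariates,
         missing_rate = missing_rate),
    class = "sim_config"
  )
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP's effect-allele dosage is drawn as Binomial(2, p); SNPs are
#' mutually independent (linkage equilibrium).
#'
#' @param n participants.
#' @param snp_panel panel data.frame (needs `snp_id`, `allele_freq`).
#' @param seed optional integer seed (NULL = current RNG stream).
#' @return integer matrix n x n_snps with SNP ids as column names.
#' @export
simulate_genotypes <- function(n, snp_panel, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_panel(snp_panel)
  with_seed(seed, {
    d <- vapply(seq_len(nrow(snp_panel)),
                function(k) stats::rbinom(n, 2L, snp_panel$allele_freq[k]),
                integer(n))
    d <- matrix(as.integer(d), nrow = n,
                dimnames = list(NULL, snp_panel$snp_id))
    d
  })
}

#' Simulate serum AFP from genotypes
#'
#' Log-linear generative model:
#' `ln(latent_i) = ln(afp_median) + sum_s d_is ln(a_s) - c + eps_i`,
#' `eps_i ~ N(0, log_noise_sd^2)`, with centering constant
#' `c = sum_s ln(E_s)` where `E_s` is the HWE population-mean genotype effect —
#' i.e. the multiplicative genetic term is exactly the individual's combined
#' normalized genetic factor G, with population mean approximately 1, so
#' `afp_median` keeps its interpretation. The observed value applies the
#' assay detection-limit floor.
#'
#' @param dosages matrix from [simulate_genotypes()].
#' @param snp_panel matching panel.
#' @param afp_median,log_noise_sd,detection_limit see [sim_config()].
#' @param seed optional seed.
#' @return data.frame with `signal` (genotype-free component
#'   `afp_median * exp(eps)`), `genetic_factor` (combined normalized genotype
#'   factor G), `latent` (= signal * genetic_factor) and `observed`
#'   (floored at the detection limit).
#' @export
simulate_afp <- function(dosages, snp_panel, afp_median = 2.70,
                         log_noise_sd = 1.0, detection_limit = 0.005,
                         seed = NULL) {
  check_panel(snp_panel)
  check_number(afp_median, "afp_median", lower = 0, strict_lower = TRUE)
  check_number(log_noise_sd, "log_noise_sd", lower = 0)
  check_number(detection_limit, "detection_limit", lower = 0, strict_lower = TRUE)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snp_panel))
    stop_("dosage matrix does not conform with the SNP panel")
  log_a <- log(snp_panel$allelic_effect)
  E <- vapply(seq_len(nrow(snp_panel)), function(k) {
    p <- snp_panel$allele_freq[k]; a <- snp_panel$allelic_effect[k]
    (1 - p)^2 + 2 * p * (1 - p) * a + p^2 * a^2
  }, 0)
  centering <- sum(log(E))
  gterm <- drop(dosages %*% log_a) - centering
  n <- nrow(dosages)
  eps <- with_seed(seed, stats::rnorm(n, 0, log_noise_sd))
  signal <- exp(log(afp_median) + eps)
  latent <- signal * exp(gterm)
  data.frame(signal = signal, genetic_factor = exp(gterm), latent = latent,
             observed = pmax(latent, detection_limit))
}

#' Solve the logistic intercept for a target marginal incidence
#'
#' Given exposures `x` and slope `beta` (per 10 ng/mL), finds `alpha` such that
#' `mean(plogis(alpha + beta * x / 10)) = target` to within 1e-6.
#'
#' @param x exposure vector (ng/mL).
#' @param beta log-odds per 10 ng/mL.
#' @param target marginal probability in (0,1).
#' @return alpha (scalar).
#' @export
solve_logistic_intercept <- function(x, beta, target) {
  check_prob(target, "target")
  marg <- function(alpha) mean(stats::plogis(alpha + beta * x / 10)) - target
  lo <- -50; hi <- 50
  if (marg(lo) > 0 || marg(hi) < 0)
    stop_("requested marginal incidence is unattainable for these exposures")
  r <- stats::uniroot(marg, c(lo, hi), tol = 1e-10)
  if (abs(marg(r$root)) > 1e-6)
    stop_("intercept solver did not reach the requested tolerance")
  r$root
}

#' Simulate the binary outcome from the genotype-free AFP component
#'
#' `P(Y = 1 | x) = plogis(alpha + log(true_or_per_10) * x / 10)`, with the
#' intercept solved so the marginal incidence over the supplied exposures
#' equals `baseline_incidence` (within 1e-6). Driving the outcome by the
#' genotype-free component makes the genetic factor pure measurement noise in
#' the observed biomarker — the situation genetic correction is meant to undo.
#'
#' @param x genotype-free AFP component, ng/mL.
#' @param true_or_per_10 generative OR per 10 ng/mL.
#' @param baseline_incidence target marginal outcome probability.
#' @param seed optional seed.
#' @return integer 0/1 vector with the solved intercept as attribute `"alpha"`.
#' @export
simulate_outcome <- function(x, true_or_per_10 = 5.0,
                             baseline_incidence = 0.00581, seed = NULL) {
  check_number(true_or_per_10, "true_or_per_10", lower = 0, strict_lower = TRUE)
  beta <- log(true_or_per_10)
  alpha <- solve_logistic_intercept(x, beta, baseline_incidence)
  pr <- stats::plogis(alpha + beta * x / 10)
  y <- with_seed(seed, stats::rbinom(length(x), 1L, pr))
  structure(as.integer(y), alpha = alpha)
}

#' Simulate baseline covariates
#'
#' Independent draws matching the configured marginals; covariates are by
#' construction independent of genotype and outcome — they exercise the
#' adjusted-model plumbing without encoding confounding.
#'
#' @param n participants.
#' @param spec covariate spec, see [default_covariate_spec()].
#' @param seed optional seed.
#' @return data.frame with one column per covariate (binary as integer 0/1).
#' @export
simulate_covariates <- function(n, spec = default_covariate_spec(),
                                seed = NULL) {
  check_number(n, "n", lower = 1)
  with_seed(seed, {
    cols <- lapply(names(spec), function(nm) {
      cv <- spec[[nm]]
      switch(cv$type,
        binary = stats::rbinom(n, 1L, cv$prevalence),
        normal = stats::rnorm(n, cv$mean, cv$sd),
        stop_(sprintf("unknown covariate type for %s", nm)))
    })
    names(cols) <- names(spec)
    as.data.frame(cols)
  })
}

#' Generate a full synthetic cohort
#'
#' Runs genotypes, AFP, covariates and outcome with independent sub-seeds
#' derived from one master seed, so the cohort is bit-identical for a given
#' `(config, seed)` pair.
#'
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @return data.frame of class `c("cohort", "data.frame")` with columns `id`,
#'   the covariates, `afp_ng_ml`, `hcc` and one dosage column per panel SNP.
#'   Latent generative components are kept in attribute `"truth"` (data.frame
#'   `signal`, `genetic_factor`, `latent`) along with `"alpha"` and `"seed"`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_participants = 500), seed = 1)
#' head(coh)
simulate_cohort <- function(config = sim_config(), seed) {
  if (!inherits(config, "sim_config")) stop_("`config` must be a sim_config")
  seeds <- derive_seeds(seed, 5)
  n <- config$n_participants
  dos <- simulate_genotypes(n, config$snp_panel, seed = seeds[1])
  afp <- simulate_afp(dos, config$snp_panel, config$afp_median,
                      config$log_noise_sd, config$detection_limit,
                      seed = seeds[2])
  cov <- simulate_covariates(n, config$covariates, seed = seeds[3])
  y <- simulate_outcome(afp$signal, config$true_or_per_10,
                        config$baseline_incidence, seed = seeds[4])
  if (config$missing_rate > 0) {
    dos <- with_seed(seeds[5], {
      miss <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow = nrow(dos))
      dos[miss] <- NA_integer_
      dos
    })
  }
  out <- data.frame(id = sprintf("P%06d", seq_len(n)), cov,
                    afp_ng_ml = afp$observed, hcc = as.integer(y),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(dos))
  class(out) <- c("cohort", "data.frame")
  attr(out, "truth") <- afp[c("signal", "genetic_factor", "latent")]
  attr(out, "alpha") <- attr(y, "alpha")
  attr(out, "seed") <- seed
  out
}

cohort_columns <- function(panel) {
  c("id", names(default_covariate_spec()), "afp_ng_ml", "hcc", panel$snp_id)
}

#' Write / read a cohort as TSV
#'
#' Plain tab-separated text with a header row; missing genotypes written as
#' `NA`. The reader validates the contract: AFP numeric and positive, outcome
#' 0/1, dosages in \{0,1,2,NA\} (violations are rejected with the offending
#' row number); AFP values at or below the detection limit are accepted but
#' reported via a message.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @param detection_limit floor used only to flag suspicious AFP values on read.
#' @return `read_cohort` returns the cohort; `write_cohort` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, detection_limit = 0.005) {
  if (!file.exists(path)) stop_("no such cohort file: ", path)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("id", "afp_ng_ml", "hcc")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_("cohort file is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$id))
    stop_("duplicated participant ids in cohort file")
  if (!is.numeric(x$afp_ng_ml) || anyNA(x$afp_ng_ml))
    stop_(sprintf("non-numeric or missing AFP at row %d",
                  which(is.na(suppressWarnings(as.numeric(x$afp_ng_ml))))[1]))
  if (any(x$afp_ng_ml <= 0))
    stop_(sprintf("non-positive AFP at row %d", which(x$afp_ng_ml <= 0)[1]))
  if (anyNA(x$hcc) || !all(x$hcc %in% c(0, 1)))
    stop_(sprintf("outcome not 0/1 at row %d",
                  which(is.na(x$hcc) | !x$hcc %in% c(0, 1))[1]))
  snp_cols <- grep("^rs[0-9]+$", names(x), value = TRUE)
  for (s in snp_cols) {
    bad <- which(!(is.na(x[[s]]) | x[[s]] %in% c(0, 1, 2)))
    if (length(bad))
      stop_(sprintf("dosage '%s' for SNP %s outside {0,1,2,NA} at row %d",
                    format(x[[s]][bad[1]]), s, bad[1]))
    x[[s]] <- as.integer(x[[s]])
  }
  n_low <- sum(x$afp_ng_ml < detection_limit)
  if (n_low > 0)
    message(sprintf("read_cohort: %d AFP value(s) below the detection limit %g",
                    n_low, detection_limit))
  class(x) <- c("cohort", "data.frame")
  x
}
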