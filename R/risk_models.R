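# Logistic risk models in the study's shape: OR per 10 ng/mL of biomarker
# under three nested covariate sets, and per-stratum fits for five subgroup
# splits. Fits are maximum-likelihood via stats::glm (IRLS); reporting is
# Wald: OR = exp(beta), CI = exp(beta +/- z * SE), two-sided p.

MODEL_COVARIATES <- list(
  model1 = character(0),
  model2 = c("age", "sex", "smoking", "drinking"),
  model3 = c("age", "sex", "smoking", "drinking",
             "education", "marriage", "bmi", "physical_activity",
             "family_history")
)

#' Covariate set for a numbered model
#'
#' Model 1 is univariate; model 2 adjusts for age, sex, smoking and drinking;
#' model 3 additionally for education, marriage, BMI, physical activity and
#' family history of cancer.
#'
#' @param model 1, 2 or 3 (or "model1"...).
#' @return character vector of covariate names.
#' @export
model_covariates <- function(model) {
  key <- if (is.numeric(model)) paste0("model", model) else as.character(model)
  if (!key %in% names(MODEL_COVARIATES))
    stop_("unknown model label: ", key)
  MODEL_COVARIATES[[key]]
}

#' Fit one logistic risk model
#'
#' Unconditional logistic regression of a binary outcome on a continuous
#' exposure (already scaled to per-10-ng/mL units) plus optional covariates.
#' Complete-case: rows with any missing model variable are dropped and the
#' remaining n is reported.
#'
#' @param outcome 0/1 vector.
#' @param exposure numeric vector in per-10-ng/mL units (i.e. AFP / 10).
#' @param covariates optional data.frame of adjustment variables.
#' @param exposure_name,model_label labels carried into the result.
#' @param level confidence level for the Wald interval.
#' @return object of class `"logistic_fit"`: list with `beta`, `se`, `or_`,
#'   `ci_low`, `ci_high`, `p`, `n_used`, `n_cases`, `converged`, labels.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         exposure_name = "exposure", model_label = "model1",
                         level = 0.95) {
  if (length(outcome) != length(exposure))
    stop_("outcome and exposure lengths differ")
  df <- data.frame(.y = outcome, .x = exposure)
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(outcome))
      stop_("covariate rows do not match outcome length")
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  check_binary_outcome(df$.y)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[".x"])
  se <- sm$coefficients[".x", "Std. Error"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  # crude separation screen: enormous SE or coefficient signals non-identified
  converged <- isTRUE(fit$converged) && is.finite(se) && se < 100 &&
    abs(beta) < 50
  structure(
    list(exposure_name = exposure_name, model_label = model_label,
         beta = beta, se = se, or_ = exp(beta),
         ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
         p = 2 * stats::pnorm(-abs(beta / se)),
         n_used = nrow(df), n_cases = sum(df$.y),
         converged = converged),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s [%s]%s\n", x$exposure_name, x$model_label,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  cat(sprintf("  OR per 10 ng/mL %.2f (95%% CI %.2f-%.2f), p = %.3g, n = %d (%d cases)\n",
              x$or_, x$ci_low, x$ci_high, x$p, x$n_used, x$n_cases))
  invisible(x)
}

logistic_fit_row <- function(f) {
  data.frame(exposure = f$exposure_name, model = f$model_label,
             beta = f$beta, se = f$se, or_ = f$or_, ci_low = f$ci_low,
             ci_high = f$ci_high, p = f$p, n_used = f$n_used,
             n_cases = f$n_cases, converged = f$converged,
             stringsAsFactors = FALSE)
}

na_fit_row <- function(exposure, model, n_used = 0L, n_cases = 0L) {
  data.frame(exposure = exposure, model = model, beta = NA_real_,
             se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p = NA_real_, n_used = n_used,
             n_cases = n_cases, converged = FALSE, stringsAsFactors = FALSE)
}

#' Run the full model battery
#'
#' One fit per exposure x model combination (by default raw and corrected AFP
#' under models 1-3, six fits), each with the biomarker scaled to per-10-ng/mL
#' units, shaped like the study's main risk table.
#'
#' @param cohort cohort data.frame; needs `hcc`, the exposure columns, and the
#'   model covariates.
#' @param exposures named character vector mapping display names to cohort
#'   column names.
#' @param models integer vector among 1:3.
#' @return data.frame with one row per fit: exposure, model, covariate set,
#'   beta, OR, Wald CI, p, n_used, n_cases, converged.
#' @export
run_model_battery <- function(cohort,
                              exposures = c(afp = "afp_ng_ml",
                                            corrected_afp = "afp_corrected_ng_ml"),
                              models = 1:3) {
  if (!"hcc" %in% names(cohort)) stop_("cohort has no `hcc` outcome column")
  rows <- list()
  for (ex in names(exposures)) {
    col <- exposures[[ex]]
    if (!col %in% names(cohort))
      stop_(sprintf("exposure column `%s` not found in cohort", col))
    for (m in models) {
      covs <- model_covariates(m)
      miss <- setdiff(covs, names(cohort))
      if (length(miss))
        stop_("cohort is missing covariate(s): ", paste(miss, collapse = ", "))
      f <- fit_logistic(cohort$hcc, cohort[[col]] / 10,
                        covariates = if (length(covs))
                          cohort[covs] else NULL,
                        exposure_name = ex, model_label = paste0("model", m))
      row <- logistic_fit_row(f)
      row$covariates <- paste(covs, collapse = "+")
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("exposure", "model", "covariates", "beta", "se", "or_", "ci_low",
          "ci_high", "p", "n_used", "n_cases", "converged")]
}

DEFAULT_SUBGROUPS <- function() list(
  sex = function(x) factor(ifelse(x$sex == 1, "male", "female"),
                           levels = c("male", "female")),
  age = function(x) factor(ifelse(x$age >= 62, ">=62", "<62"),
                           levels = c("<62", ">=62")),
  bmi = function(x) factor(ifelse(x$bmi >= 24, ">=24", "<24"),
                           levels = c("<24", ">=24")),
  smoking = function(x) factor(ifelse(x$smoking == 1, "ever", "never"),
                               levels = c("ever", "never")),
  drinking = function(x) factor(ifelse(x$drinking == 1, "ever", "never"),
                                levels = c("ever", "never"))
)

#' Subgroup analysis
#'
#' Refits the fully adjusted logistic model within strata of sex, age
#' (<62 / >=62 years), BMI (<24 / >=24 kg/m^2), smoking and drinking, with the
#' stratifying variable removed from the covariate set. Cutpoints use `>=` on
#' the upper stratum so the partition is exhaustive and disjoint. Strata
#' smaller than `min_stratum` or with a single outcome class are reported as
#' NA rows rather than errors.
#'
#' @param cohort cohort data.frame.
#' @param exposure_col biomarker column (ng/mL) to analyze.
#' @param groupings named list of functions cohort -> factor; defaults to the
#'   five study splits.
#' @param min_stratum minimum stratum size to attempt a fit.
#' @return data.frame, one row per stratum.
#' @export
subgroup_analysis <- function(cohort, exposure_col = "afp_corrected_ng_ml",
                              groupings = DEFAULT_SUBGROUPS(),
                              min_stratum = 50) {
  if (!exposure_col %in% names(cohort))
    stop_(sprintf("exposure column `%s` not found in cohort", exposure_col))
  full <- model_covariates(3)
  rows <- list()
  for (g in names(groupings)) {
    strata <- groupings[[g]](cohort)
    covs <- setdiff(full, g)
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      label <- paste0("subgroup:", g, "=", lev)
      sub <- cohort[idx, , drop = FALSE]
      if (length(idx) < min_stratum || length(unique(sub$hcc)) < 2L) {
        row <- na_fit_row(exposure_col, label, n_used = length(idx),
                          n_cases = sum(sub$hcc))
      } else {
        f <- tryCatch(
          fit_logistic(sub$hcc, sub[[exposure_col]] / 10,
                       covariates = sub[covs],
                       exposure_name = exposure_col, model_label = label),
          error = function(e) NULL)
        row <- if (is.null(f)) na_fit_row(exposure_col, label,
                                          n_used = length(idx),
                                          n_cases = sum(sub$hcc))
               else logistic_fit_row(f)
      }
      row$grouping <- g
      row$stratum <- lev
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("grouping", "stratum", "exposure", "beta", "se", "or_", "ci_low",
          "ci_high", "p", "n_used", "n_cases", "converged")]
}

#' Cumulative incidence per 1000 participants
#'
#' @param n_cases,n_total case and cohort counts.
#' @return rate per 1000, rounded half-up to 2 decimals.
#' @export
#' @examples
#' incidence_rate(57, 9819)  # 5.81
incidence_rate <- function(n_cases, n_total) {
  check_number(n_total, "n_total", lower = 0, strict_lower = TRUE)
  check_number(n_cases, "n_cases", lower = 0, upper = n_total)
  round_half_up(1000 * n_cases / n_total, 2)
}
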