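#' Default AFP SNP panel
#'
#' The two common variants associated with serum alpha-fetoprotein (AFP) used
#' for genetic correction: rs12506899 (intronic in *AFP*, chromosome 4) and
#' rs2251844 (*HISPPD2A*, chromosome 15), with their effect-allele frequencies
#' and relative allelic effects (multiplicative factor on serum AFP per copy of
#' the effect allele, from back-transformed log-scale regression).
#'
#' @return data.frame with columns `snp_id`, `chrom`, `pos_bp`, `effect_allele`,
#'   `allele_freq`, `allelic_effect`.
#' @export
#' @examples
#' afp_snp_panel()
afp_snp_panel <- function() {
  data.frame(
    snp_id = c("rs12506899", "rs2251844"),
    chrom = c("4", "15"),
    pos_bp = c(74538147L, 41623770L),
    effect_allele = c("T", "T"),
    allele_freq = c(0.33, 0.47),
    allelic_effect = c(1.08, 1.10),
    stringsAsFactors = FALSE
  )
}

check_panel <- function(panel) {
  need <- c("snp_id", "allele_freq", "allelic_effect")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop_("SNP panel is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$snp_id))
    stop_("SNP panel has duplicated snp_id")
  for (i in seq_len(nrow(panel))) {
    if (!is.finite(panel$allele_freq[i]) ||
        panel$allele_freq[i] < 0 || panel$allele_freq[i] > 1)
      stop_(sprintf("invalid effect-allele frequency %s for SNP %s",
                    format(panel$allele_freq[i]), panel$snp_id[i]))
    if (!is.finite(panel$allelic_effect[i]) || panel$allelic_effect[i] <= 0)
      stop_(sprintf("invalid allelic effect %s for SNP %s (must be > 0)",
                    format(panel$allelic_effect[i]), panel$snp_id[i]))
  }
  invisible(panel)
}

#' Normalized multiplicative genotype effects
#'
#' Under a multiplicative (log-additive) model the three genotypes act on the
#' biomarker as factors `(1, a, a^2)` for non-carriers (OO), heterozygotes (OX)
#' and homozygous carriers (XX) of the effect allele. These are normalized by
#' the population-mean effect `E = w_OO + w_OX * a + w_XX * a^2` so that the
#' weighted mean genotype effect is exactly 1 and corrected biomarker levels
#' stay on the original scale. Weights are Hardy-Weinberg proportions
#' `((1-p)^2, 2p(1-p), p^2)` or empirical genotype proportions from observed
#' counts.
#'
#' @param p effect-allele frequency in (0,1); required for `weights = "hwe"`.
#' @param a relative allelic effect (> 0); `a < 1` encodes a decreasing allele
#'   (no re-orientation is performed).
#' @param weights `"hwe"` or `"empirical"`.
#' @param counts for `weights = "empirical"`: genotype counts or proportions
#'   `c(OO, OX, XX)`.
#' @return named numeric `c(e_OO, e_OX, e_XX)` with the mean effect `E` as
#'   attribute `"mean_effect"` and the weights as attribute `"weights"`.
#' @export
#' @examples
#' genotype_effects(p = 0.33, a = 1.08)
genotype_effects <- function(p = NULL, a, weights = c("hwe", "empirical"),
                             counts = NULL) {
  weights <- match.arg(weights)
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  if (weights == "hwe") {
    check_prob(p, "p")
    w <- c(OO = (1 - p)^2, OX = 2 * p * (1 - p), XX = p^2)
  } else {
    if (is.null(counts) || length(counts) != 3L || any(!is.finite(counts)))
      stop_("`counts` must give three finite genotype counts (OO, OX, XX)")
    if (any(counts < 0)) stop_("genotype counts must be non-negative")
    w <- counts / sum(counts)
    names(w) <- c("OO", "OX", "XX")
  }
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
    stop_("degenerate genotype weights")
  raw <- c(1, a, a^2)
  E <- sum(w * raw)
  e <- raw / E
  names(e) <- c("e_OO", "e_OX", "e_XX")
  structure(e, mean_effect = E, weights = w)
}

#' Construct a SNP-effect record
#'
#' Bundles a SNP's metadata with its normalized genotype effects, checking the
#' multiplicative-model invariants: `e_OX / e_OO = a`, `e_XX / e_OO = a^2`, and
#' weighted mean effect 1. When effects are supplied directly from a published
#' table rounded to 2 decimals, use `tol = 0.005`.
#'
#' @param snp_id,chrom,pos_bp,effect_allele identifying metadata.
#' @param p effect-allele frequency.
#' @param a relative allelic effect.
#' @param effects optional `c(e_OO, e_OX, e_XX)`; computed from `(p, a)` via
#'   [genotype_effects()] when omitted.
#' @param weights,counts normalization weights, as in [genotype_effects()].
#' @param tol tolerance for the ratio/mean invariants (1e-12 for constructed
#'   effects, 0.01 for published input rounded to 2 decimals, since both the
#'   allelic effect and the genotype effects then carry half-unit rounding).
#' @return object of class `"snp_effect"`.
#' @export
snp_effect <- function(snp_id, p, a, chrom = NA_character_, pos_bp = NA_integer_,
                       effect_allele = NA_character_, effects = NULL,
                       weights = c("hwe", "empirical"), counts = NULL,
                       tol = 1e-12) {
  weights <- match.arg(weights)
  check_prob(p, "p")
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  constructed <- is.null(effects)
  if (constructed) {
    effects <- genotype_effects(p = p, a = a, weights = weights, counts = counts)
  } else {
    if (length(effects) != 3L || any(!is.finite(effects)) || any(effects <= 0))
      stop_("`effects` must be three positive values (e_OO, e_OX, e_XX)")
    names(effects) <- c("e_OO", "e_OX", "e_XX")
    if (weights == "empirical" && is.null(counts))
      stop_("empirical weights require genotype `counts`")
    w <- if (weights == "hwe") c((1 - p)^2, 2 * p * (1 - p), p^2)
         else counts / sum(counts)
    attr(effects, "weights") <- w
    attr(effects, "mean_effect") <- sum(w * effects)
  }
  # published inputs carry 2-dp rounding on BOTH a and the effects, so the
  # ratio invariant can be off by up to ~0.01 even for a consistent table
  tol_used <- if (constructed) max(tol, 1e-12) else max(tol, 0.01)
  if (abs(effects[["e_OX"]] / effects[["e_OO"]] - a) > tol_used * max(1, a) ||
      abs(effects[["e_XX"]] / effects[["e_OO"]] - a^2) > tol_used * max(1, a^2))
    stop_(sprintf("genotype effects for %s violate the multiplicative model",
                  snp_id))
  w <- attr(effects, "weights")
  mean_tol <- if (constructed) 1e-9 else 0.02
  if (abs(sum(w * effects) - 1) > mean_tol)
    stop_(sprintf("genotype effects for %s do not have population mean 1",
                  snp_id))
  structure(
    list(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
         effect_allele = effect_allele, p = p, a = a,
         e_OO = effects[["e_OO"]], e_OX = effects[["e_OX"]],
         e_XX = effects[["e_XX"]],
         weights_mode = weights, mean_effect = attr(effects, "mean_effect")),
    class = "snp_effect"
  )
}

#' @export
print.snp_effect <- function(x, ...) {
  cat(sprintf("<snp_effect> %s (chr%s:%s, allele %s)\n", x$snp_id,
              x$chrom, format(x$pos_bp, big.mark = ","), x$effect_allele))
  cat(sprintf("  p = %.3f  a = %.4f  [%s weights]\n", x$p, x$a, x$weights_mode))
  cat(sprintf("  genotype effects: OO %.4f  OX %.4f  XX %.4f\n",
              x$e_OO, x$e_OX, x$e_XX))
  invisible(x)
}

#' Estimate a relative allelic effect from a cohort
#'
#' Ordinary least squares of the natural-log biomarker on effect-allele dosage
#' (0/1/2, additive coding); the slope back-transforms to the per-allele
#' multiplicative effect `a_hat = exp(slope)`. No retransformation (smearing)
#' correction is applied.
#'
#' @param dosages integer dosages in \{0,1,2\}; `NA` rows are dropped.
#' @param biomarker positive biomarker values (same length).
#' @return list with `a_hat`, `log_a_hat`, `se_log` (standard error of the
#'   slope on the log scale), `n_used`.
#' @export
fit_allelic_effect <- function(dosages, biomarker) {
  if (length(dosages) != length(biomarker))
    stop_("`dosages` and `biomarker` lengths differ")
  keep <- !is.na(dosages) & !is.na(biomarker)
  d <- dosages[keep]; y <- biomarker[keep]
  if (!all(d %in% c(0, 1, 2)))
    stop_("dosages must be 0, 1 or 2")
  if (any(y <= 0))
    stop_("biomarker values must be positive; apply the detection-limit floor first")
  tab <- table(d)
  if (length(tab) < 2L)
    stop_("allelic effect unidentifiable: SNP is monomorphic in this cohort")
  if (length(tab) == 2L && any(tab < 10L))
    warning("only two dosage groups and one has n < 10; estimate may be unstable")
  fit <- stats::lm(log(y) ~ d)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[["d"]])
  list(a_hat = exp(slope),
       log_a_hat = slope,
       se_log = sm$coefficients["d", "Std. Error"],
       n_used = length(y))
}

#' Combine per-SNP genotype effects into one genetic factor
#'
#' An individual's combined genetic factor is the product over the panel of
#' their genotype's normalized effect. A missing genotype contributes a
#' neutral factor of 1 (the participant is retained, and the row is flagged)
#' rather than dropping the individual.
#'
#' @param snp_effects list of [snp_effect()] objects.
#' @param dosages_row integer dosages (0/1/2/NA), one per panel SNP, in panel
#'   order (names are matched when present).
#' @return combined factor `G` (> 0) with attributes `n_snps_used` and `flags`.
#' @export
combine_effects <- function(snp_effects, dosages_row) {
  if (length(dosages_row) != length(snp_effects))
    stop_("dosage row length does not match the SNP panel")
  ids <- vapply(snp_effects, `[[`, "", "snp_id")
  if (!is.null(names(dosages_row)) && all(ids %in% names(dosages_row)))
    dosages_row <- dosages_row[ids]
  G <- 1
  used <- 0L
  flags <- character(0)
  for (k in seq_along(snp_effects)) {
    d <- dosages_row[[k]]
    if (is.na(d)) {
      flags <- c(flags, sprintf("missing genotype at %s: neutral factor", ids[k]))
      next
    }
    if (!d %in% c(0, 1, 2))
      stop_(sprintf("dosage %s for SNP %s outside {0,1,2}", format(d), ids[k]))
    e <- snp_effects[[k]]
    G <- G * switch(as.character(d), "0" = e$e_OO, "1" = e$e_OX, "2" = e$e_XX)
    used <- used + 1L
  }
  structure(G, n_snps_used = used, flags = flags)
}

#' Divide a measured biomarker by a genetic factor
#'
#' @param biomarker measured value(s), ng/mL, > 0.
#' @param G combined genetic factor(s), > 0.
#' @return corrected value(s); `corrected * G` returns the input exactly.
#' @export
correct_biomarker <- function(biomarker, G) {
  if (any(!is.finite(biomarker)) || any(biomarker <= 0))
    stop_("biomarker must be positive and finite")
  if (any(!is.finite(G)) || any(G <= 0))
    stop_("genetic factor G must be positive and finite")
  biomarker / G
}

#' Percent reduction between two summary levels
#'
#' `100 * (before - after) / before`, the convention used to report how much
#' lower the corrected biomarker is than the original.
#'
#' @param before,after positive summary values (e.g. means).
#' @param digits decimals to round to (half-up); `NULL` for unrounded.
#' @export
pct_reduction <- function(before, after, digits = 1) {
  check_number(before, "before", lower = 0, strict_lower = TRUE)
  check_number(after, "after")
  out <- 100 * (before - after) / before
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Genetically correct the biomarker across a cohort
#'
#' Fits nothing: takes the panel's published/estimated `(p, a)` per SNP, forms
#' normalized genotype effects, combines them per participant and divides the
#' measured biomarker. Returns per-participant results plus a before/after
#' summary.
#'
#' @param cohort cohort data.frame (see [simulate_cohort()] / [read_cohort()]);
#'   must contain `afp_ng_ml` and one dosage column per panel SNP.
#' @param panel SNP panel data.frame as [afp_snp_panel()], or a list of
#'   [snp_effect()] objects.
#' @param weights `"hwe"` (default for published panels) or `"empirical"`
#'   (weights from the cohort's observed genotype proportions).
#' @return object of class `"cohort_correction"`: list with `result`
#'   (data.frame: `id`, `G`, `corrected`, `n_snps_used`, `flagged`), `effects`
#'   (list of snp_effect), and `summary` (mean/median/IQR before and after,
#'   `relative_change_pct`).
#' @export
cohort_correction <- function(cohort, panel = afp_snp_panel(),
                              weights = c("hwe", "empirical")) {
  weights <- match.arg(weights)
  if (!"afp_ng_ml" %in% names(cohort))
    stop_("cohort has no `afp_ng_ml` column")
  if (is.data.frame(panel)) {
    check_panel(panel)
    effects <- lapply(seq_len(nrow(panel)), function(i) {
      id <- panel$snp_id[i]
      if (!id %in% names(cohort))
        stop_(sprintf("panel SNP %s has no dosage column in the cohort", id))
      d <- cohort[[id]]
      counts <- NULL
      if (weights == "empirical")
        counts <- vapply(0:2, function(g) sum(d == g, na.rm = TRUE), 0)
      snp_effect(snp_id = id,
                 chrom = if ("chrom" %in% names(panel)) panel$chrom[i] else NA,
                 pos_bp = if ("pos_bp" %in% names(panel)) panel$pos_bp[i] else NA,
                 effect_allele = if ("effect_allele" %in% names(panel))
                   panel$effect_allele[i] else NA,
                 p = panel$allele_freq[i], a = panel$allelic_effect[i],
                 weights = weights, counts = counts)
    })
  } else {
    effects <- panel
    for (e in effects)
      if (!e$snp_id %in% names(cohort))
        stop_(sprintf("panel SNP %s has no dosage column in the cohort", e$snp_id))
  }
  ids <- vapply(effects, `[[`, "", "snp_id")
  dmat <- as.matrix(cohort[, ids, drop = FALSE])

  # vectorized product of per-genotype factors; NA dosage -> neutral 1
  G <- rep(1, nrow(dmat))
  used <- integer(nrow(dmat))
  for (k in seq_along(effects)) {
    e <- effects[[k]]
    fac <- c(e$e_OO, e$e_OX, e$e_XX)[dmat[, k] + 1L]
    miss <- is.na(fac)
    fac[miss] <- 1
    G <- G * fac
    used <- used + !miss
  }
  corrected <- correct_biomarker(cohort$afp_ng_ml, G)
  res <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else as.character(seq_along(G)),
    G = G, corrected = corrected, n_snps_used = used,
    flagged = used < length(effects),
    stringsAsFactors = FALSE
  )
  orig <- cohort$afp_ng_ml
  summ <- data.frame(
    series = c("original", "corrected"),
    mean = c(mean(orig), mean(corrected)),
    sd = c(stats::sd(orig), stats::sd(corrected)),
    median = c(stats::median(orig), stats::median(corrected)),
    q1 = c(stats::quantile(orig, 0.25, type = 7, names = FALSE),
           stats::quantile(corrected, 0.25, type = 7, names = FALSE)),
    q3 = c(stats::quantile(orig, 0.75, type = 7, names = FALSE),
           stats::quantile(corrected, 0.75, type = 7, names = FALSE))
  )
  structure(
    list(result = res, effects = effects, summary = summ,
         relative_change_pct = pct_reduction(mean(orig), mean(corrected),
                                             digits = NULL),
         weights_mode = weights),
    class = "cohort_correction"
  )
}

#' @export
print.cohort_correction <- function(x, ...) {
  cat("<cohort_correction>", nrow(x$result), "participants,",
      length(x$effects), "SNPs,", x$weights_mode, "weights\n")
  s <- x$summary
  for (i in 1:2)
    cat(sprintf("  %-9s mean %.3f  median %.3f (IQR %.3f-%.3f)\n",
                s$series[i], s$mean[i], s$median[i], s$q1[i], s$q3[i]))
  cat(sprintf("  relative change in mean: %.1f%% lower after correction\n",
              x$relative_change_pct))
  if (any(x$result$flagged))
    cat("  ", sum(x$result$flagged),
        "participant(s) with missing genotypes kept with neutral factors\n")
  invisible(x)
}

#' Table of SNP effects in publication shape
#'
#' @param effects list of [snp_effect()] (e.g. from [cohort_correction()]) or
#'   a panel data.frame plus `weights`.
#' @param digits decimals for the effect columns (NULL = unrounded).
#' @return data.frame with one row per SNP: metadata, `allele_freq`,
#'   `allelic_effect`, `e_XX`, `e_OO`, `e_OX`.
#' @export
snp_effect_table <- function(effects, digits = NULL) {
  if (is.data.frame(effects)) {
    check_panel(effects)
    effects <- lapply(seq_len(nrow(effects)), function(i)
      snp_effect(snp_id = effects$snp_id[i],
                 chrom = if ("chrom" %in% names(effects)) effects$chrom[i] else NA,
                 pos_bp = if ("pos_bp" %in% names(effects)) effects$pos_bp[i] else NA,
                 effect_allele = if ("effect_allele" %in% names(effects))
                   effects$effect_allele[i] else NA,
                 p = effects$allele_freq[i], a = effects$allelic_effect[i]))
  }
  out <- do.call(rbind, lapply(effects, function(e)
    data.frame(snp_id = e$snp_id, chrom = e$chrom, pos_bp = e$pos_bp,
               effect_allele = e$effect_allele, allele_freq = e$p,
               allelic_effect = e$a,
               e_XX = e$e_XX, e_OO = e$e_OO, e_OX = e$e_OX,
               stringsAsFactors = FALSE)))
  if (!is.null(digits))
    out[c("e_XX", "e_OO", "e_OX")] <-
      lapply(out[c("e_XX", "e_OO", "e_OX")], round_half_up, digits = digits)
  out
}
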