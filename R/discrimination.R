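# Nonparametric ROC analysis. The AUC is the Mann-Whitney estimator
# (ties count 1/2), computed via midranks in O(n log n); its variance and the
# paired-difference variance come from per-observation placement values
# (the DeLong-type decomposition), so two scores measured on the same
# participants can be compared with a two-sided normal z test.

check_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_("scores and labels lengths differ")
  if (anyNA(scores) || anyNA(labels))
    stop_("scores/labels must not contain NA")
  if (!all(labels %in% c(0, 1)))
    stop_("labels must be coded 0 (control) / 1 (case)")
  if (length(unique(labels)) < 2L)
    stop_("both classes must be present")
  invisible(NULL)
}

#' Mann-Whitney AUC via midranks
#'
#' `auc = P(score_case > score_control) + P(equal)/2`, estimated over all
#' case-control pairs but computed from midranks in O(n log n).
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 class labels.
#' @return scalar AUC in [0, 1].
#' @export
auc_midrank <- function(scores, labels) {
  check_labels(scores, labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' Placement values of cases and controls
#'
#' For the kernel `psi(X, Y) = 1[X > Y] + 1[X = Y]/2`: `V10[i]` is case i's
#' mean kernel against all controls, `V01[j]` control j's mean against all
#' cases. Both vectors average to the AUC. Computed via midranks.
#'
#' @inheritParams auc_midrank
#' @return list with `V10` (length = cases), `V01` (length = controls), `auc`.
#' @export
placement_values <- function(scores, labels) {
  check_labels(scores, labels)
  case <- labels == 1
  m <- sum(case); n <- sum(!case)
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[case], ties.method = "average")
  r_ctrl <- rank(scores[!case], ties.method = "average")
  V10 <- (r_all[case] - r_case) / n
  V01 <- 1 - (r_all[!case] - r_ctrl) / m
  auc <- (sum(r_all[case]) - m * (m + 1) / 2) / (m * n)
  list(V10 = unname(V10), V01 = unname(V01), auc = auc)
}

#' AUC with a placement-value (DeLong-type) confidence interval
#'
#' `var(auc) = var(V10)/m + var(V01)/n` with sample variances; the
#' normal-approximation CI is clipped to [0, 1]. Also reports the Youden
#' operating point.
#'
#' @inheritParams auc_midrank
#' @param level confidence level.
#' @return object of class `"roc_result"`: `auc`, `var_auc`, `ci_low`,
#'   `ci_high`, `threshold`, `sensitivity`, `specificity`, `n_cases`,
#'   `n_controls`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  pv <- placement_values(scores, labels)
  m <- length(pv$V10); n <- length(pv$V01)
  if (m < 2L || n < 2L)
    stop_("need at least 2 cases and 2 controls for a variance estimate")
  v <- stats::var(pv$V10) / m + stats::var(pv$V01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  op <- youden_operating_point(scores, labels)
  structure(
    list(auc = pv$auc, var_auc = v,
         ci_low = max(0, pv$auc - z * sqrt(v)),
         ci_high = min(1, pv$auc + z * sqrt(v)),
         threshold = op$threshold, sensitivity = op$sensitivity,
         specificity = op$specificity, n_cases = m, n_controls = n),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  cat(sprintf("  Youden point: threshold %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
              x$threshold, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Paired nonparametric comparison of two AUCs
#'
#' DeLong-type test for two scores measured on the same participants:
#' `var(delta)` combines the placement-value variances and their paired
#' covariance, `z = delta / sqrt(var(delta))`, two-sided normal p. When the
#' two scores induce identical placements (e.g. one is a monotone transform of
#' the other) the difference is exactly 0 and p = 1.
#'
#' @param scores_a,scores_b paired score vectors (same participants).
#' @param labels 0/1 labels.
#' @return object of class `"roc_comparison"`: `auc_a`, `auc_b`, `delta`
#'   (b - a), `var_a`, `var_b`, `cov_ab`, `var_delta`, `z`, `p`,
#'   `relative_change_pct` (100 * delta / auc_a), `abs_change` (delta).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop_("paired score vectors must have equal length")
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  m <- length(pa$V10); n <- length(pa$V01)
  if (m < 2L || n < 2L)
    stop_("need at least 2 cases and 2 controls")
  var_a <- stats::var(pa$V10) / m + stats::var(pa$V01) / n
  var_b <- stats::var(pb$V10) / m + stats::var(pb$V01) / n
  cov_ab <- stats::cov(pa$V10, pb$V10) / m + stats::cov(pa$V01, pb$V01) / n
  delta <- pb$auc - pa$auc
  var_delta <- max(0, var_a + var_b - 2 * cov_ab)
  if (var_delta == 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
         var_a = var_a, var_b = var_b, cov_ab = cov_ab,
         var_delta = var_delta, z = z, p = p,
         relative_change_pct = 100 * delta / pa$auc),
    class = "roc_comparison"
  )
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("<roc_comparison> AUC %.3f vs %.3f, delta %+.4f (%+.1f%%), z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$relative_change_pct, x$z, x$p))
  invisible(x)
}

#' Youden-index operating point
#'
#' Scans all distinct score values as thresholds (predict case when
#' `score >= t`) and returns the one maximizing sensitivity + specificity - 1;
#' ties are broken toward higher specificity (the larger threshold).
#'
#' @inheritParams auc_midrank
#' @return list `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_operating_point <- function(scores, labels) {
  check_labels(scores, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  o <- order(scores)
  s <- scores[o]; y <- labels[o]
  # candidate thresholds: each distinct score value, scanned descending so a
  # tie on Youden keeps the higher (more specific) threshold
  last <- !duplicated(s, fromLast = TRUE)
  thr <- s[last]
  cum_case <- cumsum(y)[last]        # cases with score <= thr... need strictly below threshold
  cum_ctrl <- cumsum(1 - y)[last]
  # at threshold t: sens = P(score >= t | case), spec = P(score < t | control)
  case_below <- c(0, cum_case[-length(cum_case)])
  ctrl_below <- c(0, cum_ctrl[-length(cum_ctrl)])
  sens <- (m - case_below) / m
  spec <- ctrl_below / n
  j <- sens + spec - 1
  best <- max(j)
  k <- max(which(j >= best - 1e-12))  # highest threshold among ties
  list(threshold = thr[k], sensitivity = sens[k], specificity = spec[k],
       youden = j[k])
}

#' Relative AUC improvement, percent
#'
#' `100 * (auc_b - auc_a) / auc_a`, rounded half-up to 1 decimal — the
#' relative-change reading of "improvement in discriminatory ability". The
#' absolute difference in AUC units is available from [delong_compare()].
#'
#' @param auc_a reference AUC (> 0); @param auc_b comparison AUC.
#' @return percent change, 1 decimal.
#' @export
#' @examples
#' relative_improvement(0.611, 0.726)  # 18.8
relative_improvement <- function(auc_a, auc_b) {
  check_number(auc_a, "auc_a", lower = 0, strict_lower = TRUE)
  check_number(auc_b, "auc_b")
  round_half_up(100 * (auc_b - auc_a) / auc_a, 1)
}

#' ROC curve coordinates
#'
#' @inheritParams auc_midrank
#' @return data.frame `threshold`, `fpr`, `tpr`, one row per distinct score
#'   plus the trivial endpoints.
#' @export
roc_curve <- function(scores, labels) {
  check_labels(scores, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  keep <- !duplicated(s)               # first index of each distinct score
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  idx <- c(which(keep)[-1] - 1L, length(y))
  data.frame(threshold = c(Inf, s[idx]),
             fpr = c(0, fp[idx] / n),
             tpr = c(0, tp[idx] / m))
}
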