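# Independent oracles used across the suite. These deliberately re-derive
# quantities by the slowest, most transparent route (exhaustive pairs,
# hand-rolled Newton-Raphson) so they share no code with the implementation.

# AUC by exhaustive case-control pair counting, O(m*n).
bf_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}

# Placement values by double loop.
bf_placements <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  V10 <- vapply(cs, function(x) mean((x > ct) + 0.5 * (x == ct)), 0)
  V01 <- vapply(ct, function(y) mean((cs > y) + 0.5 * (cs == y)), 0)
  list(V10 = V10, V01 = V01)
}

# Youden point by brute force over every distinct threshold
# (predict case when score >= t), ties toward the higher threshold.
bf_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden - 1e-12)
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   youden = j)
  }
  best
}

# Logistic MLE by plain Newton-Raphson on the log-likelihood.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, y - p))
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(g)) < tol) break
  }
  beta
}

# Small synthetic cohort config for fast tests.
quick_config <- function(n = 2000, ...) {
  sim_config(n_participants = n, ...)
}

# Panel with neutral alleles (a = 1): correction must be a no-op.
neutral_panel <- function() {
  p <- afp_snp_panel()
  p$allelic_effect <- c(1, 1)
  p
}

# Drop generator bookkeeping attributes so cohorts can be compared as data.
as_plain <- function(d) {
  d <- as.data.frame(d)
  attr(d, "truth") <- NULL
  attr(d, "alpha") <- NULL
  attr(d, "seed") <- NULL
  d
}

# Paired-score generator under the AUC-difference null: a shared component
# independent of the labels plus independent perturbations of each score.
null_paired_scores <- function(m, n) {
  base <- stats::rnorm(m + n)
  list(labels = rep(c(1, 0), c(m, n)),
       a = base + 0.5 * stats::rnorm(m + n),
       b = base + 0.5 * stats::rnorm(m + n))
}
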