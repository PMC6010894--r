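#' @keywords internal
"_PACKAGE"

# Input checking helpers. Errors are user-facing: name the offending argument
# (and SNP/row where there is one) so pipeline failures are traceable.

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower))
    stop_(sprintf("`%s` must be %s %s", name,
                  if (strict_lower) ">" else ">=", format(lower)))
  if (x > upper || (strict_upper && x >= upper))
    stop_(sprintf("`%s` must be %s %s", name,
                  if (strict_upper) "<" else "<=", format(upper)))
  invisible(x)
}

check_prob <- function(x, name, open = TRUE) {
  check_number(x, name, lower = 0, upper = 1,
               strict_lower = open, strict_upper = open)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_(sprintf("`%s` must be TRUE or FALSE", name))
  invisible(x)
}

check_binary_outcome <- function(y) {
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_("outcome must be coded 0/1 with no missing values")
  if (length(unique(y)) < 2L)
    stop_("outcome has a single class; model is not identifiable")
  invisible(as.integer(y))
}

#' Derive independent sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed. Stages that
#' need their own stream (genotypes, noise, covariates, outcome) receive
#' sub-seeds drawn once from the master seed, so adding a stage never perturbs
#' the draws of another.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  check_number(seed, "seed")
  check_number(n, "n", lower = 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr under `seed` (NULL = use the current RNG stream), restoring the
# caller's RNG state afterwards so seeded ops do not disturb the session.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable fingerprint of a configuration, recorded in report provenance.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

round_half_up <- function(x, digits = 0) {
  # round() ties to even; published tables round halves up, so acceptance
  # arithmetic (e.g. 5.805 -> 5.81) uses this instead.
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
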