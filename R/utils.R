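#' @importFrom stats cor sd rnorm runif var quantile setNames
#' @importFrom utils head tail
NULL

#' Derive a stage-specific seed from a master seed
#'
#' Fans a single master seed out to per-stage seeds so that one integer
#' reproduces a whole pipeline run while stages stay decoupled.  The
#' derivation is a small multiplicative hash of the stage label folded into
#' the master seed, kept strictly below 2^31 so it is always a valid R
#' integer seed.
#'
#' @param seed master seed (single integer).
#' @param stage character label of the stage (e.g. "ica", "qc").
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h * 7919) %% 2147483647)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Single-number check helpers used across the package.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %s is outside its allowed range", name,
                 format(x)), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_scalar(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  as.integer(x)
}

#' Frobenius norm of a matrix
#' @param x numeric matrix.
#' @return the square root of the sum of squared entries.
#' @keywords internal
frobenius <- function(x) sqrt(sum(x^2))
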