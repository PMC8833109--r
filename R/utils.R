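#' Derive a stage seed from the master seed
#'
#' All randomness in the package flows from a single master seed.  Each
#' stage (simulation, cohort split, cross-validation folds, each stability
#' iteration, ...) draws its own seed with this deterministic rule, so any
#' stage can be regenerated independently of execution order.  The rule is
#' a multiplicative hash of the master seed, a stage label, and an integer
#' index, reduced modulo 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param stage character stage label.
#' @param index integer sub-index within the stage (e.g. iteration number).
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% m
  s <- (as.numeric(seed) %% m) * 69621 %% m
  out <- (s + h * 181 + as.numeric(index) * 7919) %% (m - 1)
  as.integer(out + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## two-sided -> one-sided normal-tail p-value for H1: beta > 0
one_sided_p <- function(beta, se) {
  z <- beta / se
  pnorm(z, lower.tail = FALSE)
}
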