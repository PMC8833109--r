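## ---------------------------------------------------------------------------
## Independent-sampling (ISLSP) experiments on the exact latent predictor
## bank.  Under this null a clock is identified with the subset of latent
## predictors it samples; the variance a set of clocks explains together is
## the variance explained by the union of their subsets.  With the exact
## orthonormal bank of simulate_latent_predictor_bank() every R-squared is
## a subset-coverage fraction to machine precision.
## ---------------------------------------------------------------------------

#' Excess overlap of two subset clocks in a latent predictor bank
#'
#' Clock A samples the latent predictors in \code{subset1}, clock B those
#' in \code{subset2}.  Their individual explained variances are the
#' R-squared of chronological age on each subset (exactly |S|/p on the
#' orthonormal bank), and the joint explained variance is the R-squared on
#' the union of the subsets — under the independent-sampling null a second
#' clock can only add the predictors the first did not already sample.
#' When the intersection size equals its expectation under independent
#' sampling (|S1||S2|/p) the scaled excess overlap is exactly zero.
#'
#' @param bank result of \code{\link{simulate_latent_predictor_bank}}.
#' @param subset1,subset2 integer indices into the bank's predictors.
#' @return an \code{overlap_result} (see \code{\link{overlap_pair}}).
#' @export
islsp_overlap <- function(bank, subset1, subset2) {
  p <- ncol(bank$predictors)
  if (!length(subset1) || !length(subset2))
    stopf("both subsets must be non-empty")
  if (any(c(subset1, subset2) < 1) || any(c(subset1, subset2) > p))
    stopf("subset indices must lie in 1..%d", p)
  y <- bank$chron_age
  v1 <- r_squared(y, bank$predictors[, subset1, drop = FALSE])
  v2 <- r_squared(y, bank$predictors[, subset2, drop = FALSE])
  O <- r_squared(y, bank$predictors[, union(subset1, subset2), drop = FALSE])
  structure(
    list(clock_pair = c("subset_1", "subset_2"), v1 = v1, v2 = v2, O = O,
         E = expected_overlap(v1, v2), E_min = max(v1, v2),
         E_max = min(v1 + v2, 1), excess = excess_overlap(v1, v2, O),
         n = nrow(bank$predictors)),
    class = "overlap_result"
  )
}

#' Monte-Carlo distribution of excess overlap under independent sampling
#'
#' Repeatedly draws two independent uniform subsets of the bank's
#' predictors and evaluates the scaled excess overlap.  Under the
#' independence null the mean is approximately zero (the statistic is a
#' mildly non-linear function of the hypergeometric intersection size, so
#' individual draws fluctuate around zero).
#'
#' @param bank result of \code{\link{simulate_latent_predictor_bank}}.
#' @param size1,size2 subset sizes.
#' @param n_draws number of Monte-Carlo draws (default 200).
#' @param seed integer seed.
#' @return numeric vector of excess-overlap values, one per draw.
#' @export
islsp_monte_carlo <- function(bank, size1, size2, n_draws = 200, seed = 1L) {
  p <- ncol(bank$predictors)
  if (size1 > p || size2 > p) stopf("subset sizes must not exceed p = %d", p)
  set.seed(seed)
  vapply(seq_len(n_draws), function(i) {
    s1 <- sample.int(p, size1)
    s2 <- sample.int(p, size2)
    islsp_overlap(bank, s1, s2)$excess
  }, numeric(1))
}
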