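## ---------------------------------------------------------------------------
## Variance partitioning among clocks and the scaled excess-overlap
## statistic.  Unique (semi-partial) variances are computed via the
## leave-one-out R-squared identity: the squared part correlation of Y with
## clock i given the others equals R2(all clocks) - R2(all but clock i),
## which is numerically stable and self-checking.
## ---------------------------------------------------------------------------

r_squared <- function(y, x) {
  x <- as.matrix(x)
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

complete_clock_set <- function(chron_age, oca_set) {
  oca_set <- as.data.frame(oca_set)
  if (is.null(names(oca_set)) || any(names(oca_set) == ""))
    stopf("oca_set must be a named collection of clock age vectors")
  ok <- complete.cases(oca_set) & !is.na(chron_age)
  list(y = as.numeric(chron_age[ok]),
       x = as.matrix(oca_set[ok, , drop = FALSE]))
}

#' Unique chronAge variance explained by each clock
#'
#' The squared semi-partial (part) correlation of chronological age with
#' each clock's estimated age, controlling for all other clocks; computed
#' as the drop in multiple R-squared when the clock is removed.  A clock
#' pair that is (numerically) perfectly collinear contributes zero unique
#' variance each, with a warning.
#'
#' @param chron_age numeric vector.
#' @param oca_set named list/data.frame of estimated-age vectors, aligned
#'   with \code{chron_age}; at least two clocks.  Rows with any missing
#'   value are dropped (complete-case intersection).
#' @return named numeric vector of squared part correlations.
#' @export
unique_variance <- function(chron_age, oca_set) {
  cs <- complete_clock_set(chron_age, oca_set)
  k <- ncol(cs$x)
  if (k < 2) stopf("at least two clocks are required")
  if (nrow(cs$x) <= k + 1) stopf("too few complete cases for %d clocks", k)
  cm <- cor(cs$x)
  if (any(abs(cm[upper.tri(cm)]) > 1 - 1e-10))
    warnf("perfectly collinear clock pair: unique variances of the pair are 0")
  r2_full <- r_squared(cs$y, cs$x)
  sr2 <- vapply(seq_len(k), function(i) {
    r2_full - r_squared(cs$y, cs$x[, -i, drop = FALSE])
  }, numeric(1))
  sr2[sr2 < 0 & sr2 > -1e-9] <- 0  # numerical floor
  setNames(sr2, colnames(cs$x))
}

#' Partition chronAge variance among a set of clocks
#'
#' Decomposes the variance of chronological age into per-clock unique
#' shares (squared part correlations), a share explained by two or more
#' clocks jointly ("shared", obtained by subtraction), and the share
#' unexplained by all clocks together (1 - multiple R-squared).  The
#' components sum to one by construction.
#'
#' @inheritParams unique_variance
#' @return list of class \code{variance_partition}: \code{unique} (named),
#'   \code{r_squared}, \code{shared}, \code{unexplained}, \code{n}.
#' @export
partition_variance <- function(chron_age, oca_set) {
  cs <- complete_clock_set(chron_age, oca_set)
  if (nrow(cs$x) <= ncol(cs$x) + 1)
    stopf("n = %d is too small for %d clocks", nrow(cs$x), ncol(cs$x))
  sr2 <- unique_variance(chron_age, oca_set)
  r2 <- r_squared(cs$y, cs$x)
  shared <- r2 - sum(sr2)
  if (shared < 0 && shared > -1e-9) shared <- 0
  structure(
    list(unique = sr2, r_squared = r2, shared = shared,
         unexplained = 1 - r2, n = nrow(cs$x)),
    class = "variance_partition"
  )
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(
    "chronAge variance partition over %d clocks (n = %d):\n", length(x$unique), x$n
  ))
  cat(sprintf("  shared (>= 2 clocks): %5.1f%%\n", 100 * x$shared))
  cat(sprintf("  unique (sum):         %5.1f%%\n", 100 * sum(x$unique)))
  cat(sprintf("  unexplained:          %5.1f%%\n", 100 * x$unexplained))
  invisible(x)
}

#' Pairwise variance partition for two clocks
#'
#' @param chron_age numeric vector.
#' @param oca_i,oca_j estimated-age vectors for the two clocks.
#' @return a \code{\link{partition_variance}} result with k = 2; the
#'   shared component is attributable to both clocks jointly.
#' @export
pairwise_partition <- function(chron_age, oca_i, oca_j) {
  partition_variance(chron_age, list(clock_i = oca_i, clock_j = oca_j))
}

#' Expected joint variance under independent sampling
#'
#' Under the null that two clocks independently sample from a latent set
#' of complete predictors of chronological age, the variance left
#' unexplained after both is (1 - v1)(1 - v2), so the expected joint
#' explained variance is \code{E = 1 - (1 - v1) (1 - v2)}.
#'
#' @param v1,v2 univariate R-squared of each clock, in [0, 1].
#' @return expected joint R-squared.
#' @export
expected_overlap <- function(v1, v2) {
  if (any(c(v1, v2) < 0 | c(v1, v2) > 1)) stopf("v1 and v2 must be in [0, 1]")
  1 - (1 - v1) * (1 - v2)
}

#' Scaled excess overlap of two clocks
#'
#' Compares the observed joint explained variance O with its
#' independent-sampling expectation E = 1 - (1 - v1)(1 - v2), rescaled by
#' the attainable range: the minimum joint variance is
#' \code{E_min = max(v1, v2)} (the second clock adds nothing) and the
#' maximum is \code{E_max = min(v1 + v2, 1)} (fully complementary clocks).
#' The statistic is \code{(E - O) / (E - E_min)}: 1 means total
#' redundancy, 0 matches the independence expectation, negative values
#' mean the clocks overlap less than expected and track separate aspects
#' of ageing.
#'
#' O outside [E_min, E_max] by more than \code{tol} (sampling noise) is
#' clamped with a warning.  When \code{E == E_min} (e.g. one clock
#' explains nothing) the scale is degenerate and \code{NA} is returned
#' with a warning.
#'
#' @param v1,v2 univariate R-squared of each clock.
#' @param O observed joint (bivariate) R-squared.
#' @param tol clamping tolerance (default 1e-8).
#' @return the scaled excess overlap (dimensionless).
#' @export
excess_overlap <- function(v1, v2, O, tol = 1e-8) {
  e <- expected_overlap(v1, v2)
  e_min <- max(v1, v2)
  e_max <- min(v1 + v2, 1)
  if (O < e_min - tol || O > e_max + tol) {
    warnf("observed O = %.4g outside [E_min, E_max] = [%.4g, %.4g]; clamped",
          O, e_min, e_max)
  }
  O <- min(max(O, e_min), e_max)
  if (e - e_min <= tol) {
    warnf("degenerate scale: E = E_min = %.4g (is one clock uninformative?)", e)
    return(NA_real_)
  }
  (e - O) / (e - e_min)
}

#' Full overlap statistics for one clock pair
#'
#' @param chron_age numeric vector.
#' @param oca_i,oca_j estimated-age vectors (aligned with
#'   \code{chron_age}); complete cases only are used.
#' @param names_pair optional character(2) labels.
#' @return list of class \code{overlap_result}: \code{v1}, \code{v2}
#'   (univariate R-squared), \code{O} (bivariate R-squared), \code{E},
#'   \code{E_min}, \code{E_max}, \code{excess}.
#' @export
overlap_pair <- function(chron_age, oca_i, oca_j,
                         names_pair = c("clock_i", "clock_j")) {
  ok <- !is.na(chron_age) & !is.na(oca_i) & !is.na(oca_j)
  y <- chron_age[ok]
  v1 <- r_squared(y, oca_i[ok])
  v2 <- r_squared(y, oca_j[ok])
  O <- r_squared(y, cbind(oca_i[ok], oca_j[ok]))
  structure(
    list(clock_pair = names_pair, v1 = v1, v2 = v2, O = O,
         E = expected_overlap(v1, v2), E_min = max(v1, v2),
         E_max = min(v1 + v2, 1),
         excess = excess_overlap(v1, v2, O), n = sum(ok)),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap %s vs %s: v1=%.3f v2=%.3f O=%.3f E=%.3f excess=%.3f (n=%d)>\n",
    x$clock_pair[1], x$clock_pair[2], x$v1, x$v2, x$O, x$E, x$excess, x$n
  ))
  invisible(x)
}

#' Pairwise overlap and correlation matrices for a clock set
#'
#' Computes, for every pair of clocks, the scaled excess overlap and the
#' Pearson correlation of their age accelerations.  By convention a
#' mega-omics clock (features spanning every assay) is excluded from
#' between-clock comparisons; pass \code{exclude = character()} to keep it.
#'
#' @param chron_age numeric vector.
#' @param oca_set named list/data.frame of estimated-age vectors.
#' @param ocaa_set optional matching accelerations (defaults to
#'   \code{oca - chron_age}).
#' @param exclude clock names to drop first (default any name containing
#'   "mega").
#' @return list with \code{excess} (square matrix, unit diagonal),
#'   \code{ocaa_cor} (square correlation matrix), \code{pairs} (long-format
#'   data.frame), and \code{order} (hierarchical-clustering leaf order of
#'   the OCAA correlation matrix).
#' @export
clock_overlap_matrix <- function(chron_age, oca_set, ocaa_set = NULL,
                                 exclude = NULL) {
  oca_set <- as.data.frame(oca_set)
  if (is.null(exclude)) exclude <- grep("mega", names(oca_set), value = TRUE)
  oca_set <- oca_set[, setdiff(names(oca_set), exclude), drop = FALSE]
  k <- ncol(oca_set)
  if (k < 2) stopf("need at least two clocks after exclusions")
  if (is.null(ocaa_set)) {
    ocaa_set <- as.data.frame(lapply(oca_set, function(o) o - chron_age))
  } else {
    ocaa_set <- as.data.frame(ocaa_set)[, names(oca_set), drop = FALSE]
  }

  nm <- names(oca_set)
  excess <- matrix(1, k, k, dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      ov <- overlap_pair(chron_age, oca_set[[i]], oca_set[[j]],
                         names_pair = c(nm[i], nm[j]))
      excess[i, j] <- excess[j, i] <- ov$excess
      rows[[length(rows) + 1]] <- data.frame(
        clock_a = nm[i], clock_b = nm[j], v1 = ov$v1, v2 = ov$v2,
        O = ov$O, E = ov$E, E_min = ov$E_min, E_max = ov$E_max,
        excess = ov$excess, n = ov$n, stringsAsFactors = FALSE
      )
    }
  }
  ocaa_cor <- cor(ocaa_set, use = "pairwise.complete.obs")
  ord <- if (k > 2) stats::hclust(stats::as.dist(1 - ocaa_cor))$order
         else seq_len(k)
  list(excess = excess, ocaa_cor = ocaa_cor,
       pairs = do.call(rbind, rows), order = nm[ord])
}
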