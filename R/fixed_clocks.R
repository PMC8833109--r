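## ---------------------------------------------------------------------------
## Externally supplied fixed-coefficient clocks and the glycan-based age
## score, so published-clock-style estimated ages enter the same downstream
## analyses as clocks trained in-cohort.
## ---------------------------------------------------------------------------

#' Specify a fixed-coefficient clock
#'
#' @param clock_name label.
#' @param intercept intercept in years.
#' @param coefficients named numeric vector, feature id -> weight.
#' @param transform optional named character vector of per-feature
#'   transforms, values in \code{c("identity", "square")}; features not
#'   listed default to identity.
#' @return list of class \code{fixed_clock_spec}.
#' @export
fixed_clock_spec <- function(clock_name, intercept, coefficients,
                             transform = NULL) {
  if (length(coefficients) == 0) stopf("at least one coefficient required")
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stopf("coefficients must be named by feature id")
  if (!is.null(transform)) {
    bad <- setdiff(unique(transform), c("identity", "square"))
    if (length(bad))
      stopf("unknown transform tags: %s", paste(bad, collapse = ", "))
  }
  structure(
    list(clock_name = clock_name, intercept = intercept,
         coefficients = coefficients, transform = transform),
    class = "fixed_clock_spec"
  )
}

#' Apply a fixed-coefficient clock
#'
#' Estimated age = intercept + sum of weight * transform(feature).
#' Individuals missing any of the clock's features receive a missing
#' estimate, with a warning naming the first missing features.
#'
#' @param spec a \code{\link{fixed_clock_spec}}.
#' @param x an \code{\link{omics_matrix}} or matrix carrying the features.
#' @return named numeric vector of estimated ages.
#' @export
apply_fixed_clock <- function(spec, x) {
  v <- clock_values(x)
  feats <- names(spec$coefficients)
  absent <- setdiff(feats, colnames(v))
  if (length(absent))
    stopf("clock '%s': features absent from data: %s", spec$clock_name,
          paste(head(absent, 5), collapse = ", "))
  m <- v[, feats, drop = FALSE]
  if (!is.null(spec$transform)) {
    sq <- intersect(names(spec$transform)[spec$transform == "square"], feats)
    m[, sq] <- m[, sq, drop = FALSE]^2
  }
  n_miss <- sum(!complete.cases(m))
  if (n_miss > 0)
    warnf("clock '%s': %d individuals missing features, estimates set NA",
          spec$clock_name, n_miss)
  oca <- spec$intercept + as.numeric(m %*% spec$coefficients)
  oca[!complete.cases(m)] <- NA_real_
  setNames(oca, rownames(v))
}

#' Glycan-based age-acceleration score
#'
#' Within each sex stratum, chronological age is regressed by least
#' squares on the glycan peaks GP6, GP6 squared, GP14 and GP15; the score
#' is the fitted age minus observed chronological age, so positive values
#' mean glycan-accelerated ageing.  Being a least-squares residual (with
#' sign flipped), the score has mean zero within each sex.  If only one
#' sex is present a single unstratified fit is used.
#'
#' @param glycans data.frame with columns \code{gp6}, \code{gp14},
#'   \code{gp15}, \code{chron_age} and optionally \code{sex}; row names or
#'   an \code{individual_id} column identify individuals.
#' @return named numeric score vector (years), in input row order.
#' @export
glycan_age <- function(glycans) {
  need <- c("gp6", "gp14", "gp15", "chron_age")
  missing_cols <- setdiff(need, names(glycans))
  if (length(missing_cols))
    stopf("glycan table missing columns: %s", paste(missing_cols, collapse = ", "))
  ids <- if ("individual_id" %in% names(glycans)) glycans$individual_id
         else rownames(glycans)
  strata <- if ("sex" %in% names(glycans)) as.character(glycans$sex)
            else rep("all", nrow(glycans))
  score <- rep(NA_real_, nrow(glycans))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 5)
      stopf("fewer than 5 individuals in sex stratum '%s'", s)
    d <- glycans[idx, , drop = FALSE]
    fit <- lm(chron_age ~ gp6 + I(gp6^2) + gp14 + gp15, data = d)
    score[idx] <- fitted(fit) - d$chron_age  # = -residuals: positive = older
  }
  setNames(score, ids)
}
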