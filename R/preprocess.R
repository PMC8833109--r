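## ---------------------------------------------------------------------------
## Per-assay quality control: z-score outlier passes, fixed-effects covariate
## pre-correction, and standardisation.  The pipeline order is fixed:
## first-pass outliers -> covariate residuals -> optional second-pass
## outliers (on the residual distribution) -> standardise.
## ---------------------------------------------------------------------------

#' Mask outliers in one feature by z-score
#'
#' Entries whose absolute z-score (computed from the non-missing mean and
#' SD of the vector itself) exceeds the threshold are set to \code{NA};
#' everything else is untouched.  A single pass: statistics are not
#' recomputed after masking.  Constant and all-missing vectors are returned
#' unchanged (with a warning for the latter).
#'
#' @param x numeric vector, possibly with \code{NA}.
#' @param z_threshold positive z-score cut-off (default 6).
#' @return \code{x} with outliers replaced by \code{NA}.
#' @export
remove_outliers <- function(x, z_threshold = 6) {
  if (z_threshold <= 0) stopf("z_threshold must be > 0")
  ok <- !is.na(x)
  if (!any(ok)) {
    warnf("all-missing feature left unchanged by outlier pass")
    return(x)
  }
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (is.na(s) || s == 0) return(x)  # constant feature: nothing to flag
  z <- abs(x - m) / s
  x[ok & z > z_threshold] <- NA
  x
}

#' Pre-correct features for covariates by fixed-effects regression
#'
#' Each feature is replaced by the residuals of an ordinary least-squares
#' fit on the named covariate columns of the matrix's covariate table
#' (factors are expanded to indicators).  Individuals with a missing
#' feature value keep \code{NA}; individuals missing a covariate are also
#' set \code{NA} for every feature.  Aliased (rank-deficient) design
#' columns are dropped by the fit and recorded in the
#' \code{"aliased"} attribute of the result.
#'
#' @param mat an \code{\link{omics_matrix}} with a covariate table.
#' @param covariate_names character vector of covariate column names.
#' @return an \code{omics_matrix} of residuals (same dimensions and ids).
#' @export
precorrect_covariates <- function(mat, covariate_names) {
  if (!inherits(mat, "omics_matrix")) stopf("mat must be an omics_matrix")
  if (is.null(mat$covariates)) stopf("assay '%s' has no covariates", mat$assay_name)
  missing_cov <- setdiff(covariate_names, colnames(mat$covariates))
  if (length(missing_cov))
    stopf("covariates not found in assay '%s': %s", mat$assay_name,
          paste(missing_cov, collapse = ", "))
  cov <- mat$covariates[, covariate_names, drop = FALSE]
  design <- model.matrix(~ ., data = cov)  # drops rows with missing covariates
  keep <- rownames(design)

  out <- mat$values
  out[] <- NA_real_
  aliased <- character()
  vals <- mat$values[keep, , drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    y <- vals[, j]
    ok <- !is.na(y)
    if (sum(ok) <= ncol(design)) next
    fit <- stats::lm.fit(design[ok, , drop = FALSE], y[ok])
    if (any(is.na(fit$coefficients)))
      aliased <- union(aliased, names(fit$coefficients)[is.na(fit$coefficients)])
    out[keep[ok], j] <- fit$residuals
  }
  res <- omics_matrix(out, assay_name = mat$assay_name,
                      covariates = mat$covariates)
  attr(res, "aliased") <- aliased
  res
}

#' Standardise features to mean zero, SD one
#'
#' Scales and centres every feature over its non-missing entries.
#' Features that are constant (zero SD) carry no information and are
#' dropped; their ids are recorded in the \code{"dropped"} attribute.
#'
#' @param mat an \code{\link{omics_matrix}}.
#' @return an \code{omics_matrix} with standardised (and possibly fewer)
#'   features.
#' @export
standardize_features <- function(mat) {
  if (!inherits(mat, "omics_matrix")) stopf("mat must be an omics_matrix")
  v <- mat$values
  mu <- colMeans(v, na.rm = TRUE)
  sds <- apply(v, 2, sd, na.rm = TRUE)
  constant <- is.na(sds) | sds == 0
  v <- sweep(v[, !constant, drop = FALSE], 2, mu[!constant])
  v <- sweep(v, 2, sds[!constant], "/")
  res <- omics_matrix(v, assay_name = mat$assay_name,
                      covariates = mat$covariates)
  attr(res, "dropped") <- colnames(mat$values)[constant]
  res
}

#' Configure the QC pipeline for one assay
#'
#' @param z_first_pass z-score threshold for the first outlier pass
#'   (default 6).
#' @param z_second_pass optional z-score threshold applied to the
#'   post-correction residuals (default \code{NULL} = disabled; 3 where
#'   enabled).
#' @param covariate_names covariates to pre-correct for.  Sex is always a
#'   pre-correction covariate for features; it remains available as a model
#'   covariate downstream.
#' @return a list of class \code{qc_config}.
#' @export
qc_config <- function(z_first_pass = 6, z_second_pass = NULL,
                      covariate_names = c("sex", "batch")) {
  if (z_first_pass <= 0) stopf("z_first_pass must be > 0")
  if (!is.null(z_second_pass) && z_second_pass <= 0)
    stopf("z_second_pass must be > 0 when enabled")
  structure(
    list(z_first_pass = z_first_pass, z_second_pass = z_second_pass,
         covariate_names = covariate_names),
    class = "qc_config"
  )
}

#' Run the full QC pipeline on one assay
#'
#' Fixed order: first-pass z-score outlier masking, covariate
#' pre-correction, optional second-pass outlier masking on the residuals,
#' standardisation.  Individual order is never altered.  A QC report
#' (outlier counts per pass, dropped constant features, aliased design
#' columns) is attached as the \code{"qc_report"} attribute.
#'
#' @param mat an \code{\link{omics_matrix}}.
#' @param config a \code{\link{qc_config}}.
#' @return the corrected, standardised \code{omics_matrix}.
#' @export
qc_pipeline <- function(mat, config = qc_config()) {
  if (!inherits(config, "qc_config")) stopf("config must be a qc_config")
  n_na0 <- sum(is.na(mat$values))

  v <- apply(mat$values, 2, remove_outliers, z_threshold = config$z_first_pass)
  dimnames(v) <- dimnames(mat$values)
  n_na1 <- sum(is.na(v))
  step1 <- omics_matrix(v, mat$assay_name, mat$covariates)

  step2 <- precorrect_covariates(step1, config$covariate_names)
  n_na2 <- sum(is.na(step2$values))

  if (!is.null(config$z_second_pass)) {
    v <- apply(step2$values, 2, remove_outliers,
               z_threshold = config$z_second_pass)
    dimnames(v) <- dimnames(step2$values)
    aliased <- attr(step2, "aliased")
    step2 <- omics_matrix(v, mat$assay_name, mat$covariates)
    attr(step2, "aliased") <- aliased
  }
  n_na3 <- sum(is.na(step2$values))

  out <- standardize_features(step2)
  attr(out, "qc_report") <- list(
    assay = mat$assay_name,
    n_missing_input = n_na0,
    n_outliers_first_pass = n_na1 - n_na0,
    n_missing_covariates = n_na2 - n_na1,
    n_outliers_second_pass = n_na3 - n_na2,
    dropped_constant_features = attr(out, "dropped"),
    aliased_covariates = attr(step2, "aliased") %||% character()
  )
  out
}
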