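#' Construct an omics feature matrix
#'
#' Lightweight container for one assay: an individuals x features numeric
#' matrix plus the per-individual covariates used for pre-correction
#' (sex, batch, smoking, ...).  Row names are individual ids and column
#' names feature ids; both are mandatory and unique.
#'
#' @param values numeric matrix, individuals in rows, features in columns,
#'   with row and column names.  May contain \code{NA}.
#' @param assay_name label for the assay.
#' @param covariates data.frame of per-individual covariates, one row per
#'   row of \code{values} (matched by row name when named).
#' @return an object of class \code{omics_matrix}.
#' @export
omics_matrix <- function(values, assay_name = "assay", covariates = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("omics matrix values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("omics matrix needs row (individual) and column (feature) names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate individual ids in assay '%s'", assay_name)
  if (anyDuplicated(colnames(values)))
    stopf("duplicate feature ids in assay '%s'", assay_name)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      stopf("covariates must have one row per individual")
    if (!is.null(rownames(covariates)) &&
        !identical(rownames(covariates), rownames(values)))
      covariates <- covariates[rownames(values), , drop = FALSE]
  }
  structure(
    list(assay_name = assay_name, values = values, covariates = covariates),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix '%s': %d individuals x %d features, %d missing values>\n",
    x$assay_name, nrow(x$values), ncol(x$values), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

individual_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)
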