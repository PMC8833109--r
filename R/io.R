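## ---------------------------------------------------------------------------
## File formats: tab-separated tables with a header row, UTF-8, missing
## values as empty fields.  Clock models serialise to JSON; configurations
## to YAML.
## ---------------------------------------------------------------------------

#' Write a data table in the package's TSV dialect
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
}

#' Read a table written by \code{\link{write_tsv}}
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = "",
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Write all tables of a simulated cohort
#'
#' Emits cohort.tsv, truth.tsv, riskfactors.tsv, disease.tsv, one
#' \code{<assay>.features.tsv} (first column individual_id) plus
#' \code{<assay>.covariates.tsv} per assay, and config.yaml.
#'
#' @param sim an \code{ocaa_simulation}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  w <- function(x, name) {
    p <- file.path(dir, name)
    write_tsv(x, p)
    files <<- c(files, p)
  }
  w(sim$cohort, "cohort.tsv")
  w(sim$truth, "truth.tsv")
  w(sim$risk_factors, "riskfactors.tsv")
  w(sim$disease, "disease.tsv")
  for (a in sim$omics) {
    feat <- data.frame(individual_id = rownames(a$values),
                       a$values, check.names = FALSE,
                       stringsAsFactors = FALSE)
    w(feat, paste0(a$assay_name, ".features.tsv"))
    if (!is.null(a$covariates)) {
      cov <- data.frame(individual_id = rownames(a$values),
                        a$covariates, check.names = FALSE,
                        stringsAsFactors = FALSE)
      w(cov, paste0(a$assay_name, ".covariates.tsv"))
    }
  }
  write_config(sim$config, file.path(dir, "config.yaml"))
  invisible(c(files, file.path(dir, "config.yaml")))
}

#' Read simulated-cohort tables back from disk
#'
#' @param dir directory written by \code{\link{write_simulation}}.
#' @return an \code{ocaa_simulation}-shaped list (truth.tsv is read only
#'   if present).
#' @export
read_simulation <- function(dir) {
  cohort <- read_tsv(file.path(dir, "cohort.tsv"))
  cohort$sex <- factor(cohort$sex, levels = c("F", "M"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv(truth_path) else NULL
  config <- read_config(file.path(dir, "config.yaml"))
  omics <- list()
  for (a in config$assays) {
    feat <- read_tsv(file.path(dir, paste0(a$name, ".features.tsv")))
    v <- as.matrix(feat[, -1, drop = FALSE])
    rownames(v) <- feat$individual_id
    cov_path <- file.path(dir, paste0(a$name, ".covariates.tsv"))
    covars <- NULL
    if (file.exists(cov_path)) {
      cv <- read_tsv(cov_path)
      covars <- cv[, -1, drop = FALSE]
      covars$sex <- factor(covars$sex, levels = c("F", "M"))
      covars$batch <- factor(covars$batch)
      rownames(covars) <- cv$individual_id
    }
    omics[[a$name]] <- omics_matrix(v, assay_name = a$name,
                                    covariates = covars)
  }
  structure(
    list(cohort = cohort, truth = truth, omics = omics,
         risk_factors = read_tsv(file.path(dir, "riskfactors.tsv")),
         disease = read_tsv(file.path(dir, "disease.tsv")),
         config = config),
    class = "ocaa_simulation"
  )
}

#' Write a simulation configuration as YAML
#'
#' @param config a \code{\link{simulation_config}}.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$assays <- lapply(config$assays, unclass)
  out$risk_factors <- lapply(config$risk_factors, unclass)
  out$diseases <- lapply(config$diseases, unclass)
  yaml::write_yaml(out, path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML path.
#' @return a \code{\link{simulation_config}}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulation_config(
    n_individuals = y$n_individuals,
    age_range = unlist(y$age_range),
    sigma_delta = y$sigma_delta,
    assays = lapply(y$assays, function(a) do.call(assay_spec, a)),
    risk_factors = lapply(y$risk_factors, function(r)
      do.call(risk_factor_spec, r)),
    diseases = lapply(y$diseases, function(d) do.call(disease_spec, d)),
    followup_years = y$followup_years,
    seed = y$seed
  )
}

#' Serialise a fitted clock to JSON
#'
#' @param clock an \code{omics_clock}.
#' @param path output path.
#' @export
clock_to_json <- function(clock, path) {
  payload <- list(
    assay_name = clock$assay_name, method = clock$method,
    alpha = clock$alpha, lambda = clock$lambda,
    intercept = clock$intercept,
    coefficients = as.list(clock$coefficients),
    feature_center = as.list(clock$feature_center),
    feature_scale = as.list(clock$feature_scale),
    train_ids = clock$train_ids, test_ids = clock$test_ids,
    train_r = clock$train_r, test_r = clock$test_r, seed = clock$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Restore a clock serialised by \code{\link{clock_to_json}}
#'
#' @param path JSON path.
#' @return an \code{omics_clock}.
#' @export
clock_from_json <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(assay_name = y$assay_name, method = y$method, alpha = y$alpha,
         lambda = y$lambda, intercept = y$intercept,
         coefficients = unlist(y$coefficients) %||% setNames(numeric(0), character(0)),
         feature_center = unlist(y$feature_center),
         feature_scale = unlist(y$feature_scale),
         train_ids = y$train_ids, test_ids = y$test_ids,
         train_r = y$train_r, test_r = y$test_r, seed = y$seed),
    class = "omics_clock"
  )
}
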