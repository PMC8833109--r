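## ---------------------------------------------------------------------------
## End-to-end orchestration: simulate -> QC -> clocks (standard, core, PC,
## mega) -> age tables -> variance partition / overlap -> screening ->
## associations -> report.  Every stage writes plain-text intermediates to
## the run directory and is skipped on re-run when its outputs already
## exist, so a deleted stage is recomputed without redoing the rest.
## ---------------------------------------------------------------------------

stage_files <- function(run_dir) {
  list(
    simulate = file.path(run_dir, "data", "config.yaml"),
    preprocess = file.path(run_dir, "corrected", "qc_report.json"),
    clocks = file.path(run_dir, "clocks", "clock_ages.tsv"),
    overlap = file.path(run_dir, "overlap", "overlap_pairs.tsv"),
    associations = file.path(run_dir, "associations", "associations.tsv")
  )
}

#' Run the full analysis pipeline
#'
#' @param config a \code{\link{simulation_config}} or the path to a YAML
#'   configuration file.
#' @param run_dir output directory for all stage artifacts.
#' @param stability_iterations repeats for core-clock stability selection
#'   (0 disables core clocks; default 50).
#' @param pc_components number of principal components for the PC clocks
#'   (0 disables; default 3).
#' @param pooled_divisor magnitude of the pooled per-year chronAge log
#'   hazard ratio used to rescale disease effects; \code{NULL} (default)
#'   estimates it as the inverse-variance-weighted mean of the per-disease
#'   chronAge effects from the screening stage.
#' @param q FDR level for screening and association families.
#' @param resume when \code{TRUE} (default) stages whose outputs already
#'   exist are loaded instead of recomputed.
#' @return invisibly, the run manifest (also written as manifest.json).
#' @export
run_pipeline <- function(config, run_dir, stability_iterations = 50,
                         pc_components = 3, pooled_divisor = NULL,
                         q = 0.10, resume = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "simulation_config"))
    stopf("config must be a simulation_config or a YAML path")
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  sf <- stage_files(run_dir)
  seed <- config$seed

  ## -- stage: simulate -----------------------------------------------------
  data_dir <- file.path(run_dir, "data")
  if (!resume || !file.exists(sf$simulate)) {
    sim <- simulate_cohort(config)
    write_simulation(sim, data_dir)
  }
  ## downstream stages always consume the on-disk representation, so a
  ## resumed run is byte-identical to a fresh one
  sim <- read_simulation(data_dir)
  cohort <- sim$cohort
  chron_age <- setNames(cohort$chron_age, cohort$individual_id)
  sex <- setNames(cohort$sex, cohort$individual_id)
  smoking <- setNames(cohort$smoking, cohort$individual_id)

  ## -- stage: preprocess ---------------------------------------------------
  corr_dir <- file.path(run_dir, "corrected")
  if (!resume || !file.exists(sf$preprocess)) {
    dir.create(corr_dir, showWarnings = FALSE)
    reports <- list()
    for (a in sim$omics) {
      out <- qc_pipeline(a, qc_config(z_first_pass = 6, z_second_pass = 3,
                                      covariate_names = c("sex", "batch")))
      reports[[a$assay_name]] <- attr(out, "qc_report")
      feat <- data.frame(individual_id = rownames(out$values), out$values,
                         check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(feat, file.path(corr_dir, paste0(a$assay_name, ".features.tsv")))
    }
    jsonlite::write_json(reports, sf$preprocess, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  corrected <- lapply(sim$omics, function(a) {
    feat <- read_tsv(file.path(corr_dir, paste0(a$assay_name, ".features.tsv")))
    v <- as.matrix(feat[, -1, drop = FALSE])
    rownames(v) <- feat$individual_id
    omics_matrix(v, a$assay_name, a$covariates)
  })
  names(corrected) <- names(sim$omics)

  ## -- stage: clocks -------------------------------------------------------
  clock_dir <- file.path(run_dir, "clocks")
  if (!resume || !file.exists(sf$clocks)) {
    dir.create(clock_dir, showWarnings = FALSE)
    complete_ids <- Reduce(intersect, lapply(corrected, function(a)
      rownames(a$values)[complete.cases(a$values)]))
    sp <- split_cohort(cohort$individual_id, fraction = 0.75,
                       complete_ids = complete_ids,
                       seed = derive_seed(seed, "pipeline_split"))

    clocks <- list()
    ages <- list()
    summaries <- list()
    add_clock <- function(fit, x, name) {
      clocks[[name]] <<- fit
      ages[[name]] <<- clock_age_table(fit, x, chron_age,
                                       ids = fit$test_ids, clock_name = name)
      summaries[[name]] <<- data.frame(
        clock_name = name, n_train = length(fit$train_ids),
        n_test = length(fit$test_ids),
        n_features_available = if (inherits(x, "omics_matrix"))
          ncol(x$values) else ncol(x),
        n_features_selected = length(fit$coefficients),
        train_r = fit$train_r, test_r = fit$test_r,
        stringsAsFactors = FALSE
      )
      if (!inherits(fit, "pc_clock"))
        clock_to_json(fit, file.path(clock_dir, paste0(name, ".json")))
    }

    for (a in corrected) {
      fit <- omics_clock(a, chron_age, train_ids = sp$train_ids,
                         test_ids = sp$test_ids,
                         seed = derive_seed(seed, "clock", match(a$assay_name,
                                                                 names(corrected))))
      add_clock(fit, a, a$assay_name)
      if (stability_iterations > 0) {
        ## an assay with no stably selected feature simply gets no core clock
        st <- tryCatch(
          stability_select(a, chron_age,
                           iterations = stability_iterations,
                           seed = derive_seed(seed, "stability_stage")),
          error = function(e) {
            message(sprintf("no core clock for '%s': %s", a$assay_name,
                            conditionMessage(e)))
            NULL
          }
        )
        if (!is.null(st))
          add_clock(st$core_clock, a$values[, st$core_features, drop = FALSE],
                    paste0(a$assay_name, "_core"))
      }
      if (pc_components > 0) {
        pcfit <- pc_clock(a, pc_components, chron_age,
                          train_ids = sp$train_ids, test_ids = sp$test_ids,
                          seed = derive_seed(seed, "pc_clock"))
        add_clock(pcfit, a, pcfit$assay_name)
      }
    }
    if (length(corrected) > 1) {
      mega <- build_mega_matrix(corrected)
      fit <- omics_clock(mega, chron_age, train_ids = sp$train_ids,
                         test_ids = sp$test_ids,
                         seed = derive_seed(seed, "mega"))
      add_clock(fit, mega, "mega_omics")
      shares <- mega_feature_shares(fit)
      jsonlite::write_json(as.list(shares),
                           file.path(clock_dir, "mega_feature_shares.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    clock_ages <- do.call(rbind, ages)
    rownames(clock_ages) <- NULL
    write_tsv(clock_ages, sf$clocks)
    clock_summary <- do.call(rbind, summaries)
    rownames(clock_summary) <- NULL
    write_tsv(clock_summary, file.path(clock_dir, "clock_summary.tsv"))
  }
  clock_ages <- read_tsv(sf$clocks)

  ## -- stage: partition / overlap ------------------------------------------
  ov_dir <- file.path(run_dir, "overlap")
  ## standard per-assay clocks only enter between-clock comparisons
  standard <- names(sim$omics)
  if (!resume || !file.exists(sf$overlap)) {
    dir.create(ov_dir, showWarnings = FALSE)
    oca_wide <- reshape_ages(clock_ages, "oca")
    std_cols <- intersect(standard, names(oca_wide))
    y <- chron_age[rownames(oca_wide)]
    om <- clock_overlap_matrix(y, oca_wide[, std_cols, drop = FALSE],
                               exclude = character())
    write_tsv(om$pairs, sf$overlap)
    write_square(om$excess, file.path(ov_dir, "excess_matrix.tsv"))
    write_square(om$ocaa_cor, file.path(ov_dir, "ocaa_cor.tsv"))
    part <- partition_variance(y, oca_wide[, std_cols, drop = FALSE])
    jsonlite::write_json(
      list(unique = as.list(part$unique), r_squared = part$r_squared,
           shared = part$shared, unexplained = part$unexplained, n = part$n),
      file.path(ov_dir, "partition.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  }

  ## -- stage: screening + associations -------------------------------------
  as_dir <- file.path(run_dir, "associations")
  if (!resume || !file.exists(sf$associations)) {
    dir.create(as_dir, showWarnings = FALSE)
    screen <- screen_outcomes(sim$risk_factors, sim$disease, chron_age, sex,
                              q = q)
    write_tsv(screen, file.path(as_dir, "screen.tsv"))
    if (is.null(pooled_divisor)) {
      dz <- screen[screen$outcome_type == "disease" & screen$eligible, ,
                   drop = FALSE]
      pooled_divisor <- if (nrow(dz)) abs(ivw_mean(dz$chron_age_beta,
                                                   dz$se)$pooled_beta)
                        else 0.0492
    }
    assoc <- associate_all(clock_ages, screen, sim$risk_factors, sim$disease,
                           chron_age, sex, pooled_divisor = pooled_divisor,
                           q = q)
    write_tsv(assoc, sf$associations)
    enr <- enrichment_summary(assoc)
    write_tsv(enr, file.path(as_dir, "enrichment.tsv"))
    ivw <- do.call(rbind, lapply(split(assoc, list(assoc$clock_name,
                                                   assoc$outcome_type),
                                       drop = TRUE), function(r) {
      m <- ivw_mean(r$rescaled_beta, r$se / abs(r$beta / r$rescaled_beta))
      data.frame(clock_name = r$clock_name[1],
                 outcome_type = r$outcome_type[1], n = nrow(r),
                 ivw_rescaled_beta = m$pooled_beta,
                 indicative_se = m$indicative_se, stringsAsFactors = FALSE)
    }))
    rownames(ivw) <- NULL
    write_tsv(ivw, file.path(as_dir, "ivw.tsv"))
    sexcheck <- sex_sign_consistency(assoc, clock_ages, sim$disease,
                                     chron_age, sex, q = q)
    jsonlite::write_json(
      list(n_assessed = sexcheck$n_assessed,
           prop_consistent = sexcheck$prop_consistent),
      file.path(as_dir, "sex_consistency.json"), auto_unbox = TRUE,
      digits = NA
    )
  }

  ## -- report + manifest ---------------------------------------------------
  report_run(run_dir)
  manifest <- build_manifest(run_dir, config)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

reshape_ages <- function(clock_ages, value = "oca") {
  ids <- sort(unique(clock_ages$individual_id))
  clocks <- unique(clock_ages$clock_name)
  out <- data.frame(row.names = ids)
  for (cl in clocks) {
    sub <- clock_ages[clock_ages$clock_name == cl, , drop = FALSE]
    out[[cl]] <- sub[[value]][match(ids, sub$individual_id)]
  }
  out
}

write_square <- function(m, path) {
  write_tsv(data.frame(clock = rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
}

read_square <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$clock
  m
}

build_manifest <- function(run_dir, config) {
  files <- list.files(run_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  digests <- as.list(setNames(unname(tools::md5sum(files)),
                              substring(files, nchar(run_dir) + 2)))
  list(
    package_version = as.character(utils::packageVersion("ocaa")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(file.path(run_dir, "data",
                                                 "config.yaml"))),
    files = digests
  )
}

#' Emit the report tables and summary for a finished run
#'
#' Writes, under \code{<run_dir>/report}: a clock performance table (one
#' row per clock: sizes, features selected, train/test chronAge
#' correlation), the OCAA correlation matrix, the excess-overlap matrix
#' (unit diagonal by construction), the association grid restricted to
#' screened-eligible outcomes, and a plain-text summary of the variance
#' partition, enrichment statistics and IVW mean effects.
#'
#' @param run_dir directory of a (partially) completed
#'   \code{\link{run_pipeline}} run.
#' @return invisibly, the report directory path.
#' @export
report_run <- function(run_dir) {
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(p) {
    if (!file.exists(p))
      stopf("missing upstream artifact '%s'; run the producing stage first", p)
    p
  }
  clock_summary <- read_tsv(need(file.path(run_dir, "clocks",
                                           "clock_summary.tsv")))
  write_tsv(clock_summary, file.path(rep_dir, "clock_performance.tsv"))
  file.copy(need(file.path(run_dir, "overlap", "ocaa_cor.tsv")),
            file.path(rep_dir, "ocaa_correlations.tsv"), overwrite = TRUE)
  file.copy(need(file.path(run_dir, "overlap", "excess_matrix.tsv")),
            file.path(rep_dir, "excess_overlap.tsv"), overwrite = TRUE)
  assoc <- read_tsv(need(file.path(run_dir, "associations",
                                   "associations.tsv")))
  write_tsv(assoc, file.path(rep_dir, "association_grid.tsv"))

  part <- jsonlite::read_json(need(file.path(run_dir, "overlap",
                                             "partition.json")),
                              simplifyVector = TRUE)
  enr <- read_tsv(need(file.path(run_dir, "associations", "enrichment.tsv")))
  ivw <- read_tsv(need(file.path(run_dir, "associations", "ivw.tsv")))

  lines <- c(
    "Run summary",
    "===========",
    sprintf("Clocks fitted: %d (test chronAge r range %.2f-%.2f)",
            nrow(clock_summary), min(clock_summary$test_r, na.rm = TRUE),
            max(clock_summary$test_r, na.rm = TRUE)),
    sprintf("chronAge variance: %.1f%% shared, %.1f%% unique, %.1f%% unexplained",
            100 * part$shared, 100 * sum(unlist(part$unique)),
            100 * part$unexplained),
    "",
    "Enrichment of positive OCAA effects:",
    sprintf("  %s: %.1f%% positive, %.1f%% nominally significant (n=%d)",
            enr$outcome_type, 100 * enr$prop_positive,
            100 * enr$prop_nominal, enr$n_tests),
    "",
    "IVW mean rescaled effects (years of chronAge per year of OCAA):",
    sprintf("  %s / %s: %.3f (~SE %.3f, n=%d)", ivw$clock_name,
            ivw$outcome_type, ivw$ivw_rescaled_beta, ivw$indicative_se,
            ivw$n)
  )
  writeLines(lines, file.path(rep_dir, "summary.txt"))
  invisible(rep_dir)
}
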