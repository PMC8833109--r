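## ---------------------------------------------------------------------------
## Synthetic cohort generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a cohort with a wide age range, several omics assays whose
## features load both on chronological age and on a single latent
## biological-age acceleration ("delta", in years), risk factors linear in
## age and delta, and incident disease with proportional hazards in age and
## delta, censoring at end of follow-up, and pre-baseline prevalent cases.
## ---------------------------------------------------------------------------

#' Specify a synthetic omics assay
#'
#' Feature j of an assay is generated as
#' \deqn{x_j = a_j z(age) + b_j z(delta) + batch_j + e_j}
#' where \eqn{z()} standardises over the cohort, the loadings \eqn{a_j, b_j}
#' are drawn once per feature from half-normal distributions with the given
#' scales, the batch offset is drawn per feature and batch level, and
#' \eqn{e_j} is Gaussian noise.  Raising \code{age_loading_scale} relative
#' to \code{noise_sd} makes the assay a better chronological-age predictor;
#' raising \code{delta_loading_scale} makes its clock's age acceleration
#' track the latent delta more closely.
#'
#' @param name assay label.
#' @param n_features number of features (>= 1).
#' @param age_loading_scale half-normal scale of the age loadings.
#' @param delta_loading_scale half-normal scale of the delta loadings.
#' @param noise_sd residual feature noise SD (> 0).
#' @param batch_levels number of batch levels (1 disables batch effects).
#' @param batch_sd SD of the per-feature, per-level batch offsets.
#' @return a list of class \code{assay_spec}.
#' @export
assay_spec <- function(name, n_features, age_loading_scale,
                       delta_loading_scale, noise_sd = 1,
                       batch_levels = 1L, batch_sd = 0.3) {
  if (n_features < 1) stopf("assay '%s': n_features must be >= 1", name)
  if (noise_sd <= 0) stopf("assay '%s': noise_sd must be > 0", name)
  if (age_loading_scale < 0 || delta_loading_scale < 0)
    stopf("assay '%s': loading scales must be >= 0", name)
  if (batch_levels < 1) stopf("assay '%s': batch_levels must be >= 1", name)
  structure(
    list(name = name, n_features = as.integer(n_features),
         age_loading_scale = age_loading_scale,
         delta_loading_scale = delta_loading_scale,
         noise_sd = noise_sd, batch_levels = as.integer(batch_levels),
         batch_sd = batch_sd),
    class = "assay_spec"
  )
}

#' Specify a synthetic risk factor
#'
#' Risk factor value = \code{beta_age * chron_age + beta_delta * delta +
#' N(0, noise_sd^2)}, on a scale whose noise SD is 1 by default so that
#' \code{beta_age} reads approximately as SD units per year.
#'
#' @param name risk factor label.
#' @param beta_age effect of one year of chronological age.
#' @param beta_delta effect of one year of latent acceleration.
#' @param noise_sd residual SD.
#' @return a list of class \code{risk_factor_spec}.
#' @export
risk_factor_spec <- function(name, beta_age, beta_delta, noise_sd = 1) {
  if (noise_sd <= 0) stopf("risk factor '%s': noise_sd must be > 0", name)
  structure(
    list(name = name, beta_age = beta_age, beta_delta = beta_delta,
         noise_sd = noise_sd),
    class = "risk_factor_spec"
  )
}

#' Specify a synthetic disease
#'
#' Event times are exponential with per-individual rate
#' \code{baseline_rate * exp(log_hr_age * chron_age + log_hr_delta * delta)},
#' censored at end of follow-up.  The same hazard is run backwards over
#' \code{prevalence_window_years} before baseline to generate prevalent
#' cases, which downstream analyses must exclude.
#'
#' @param name disease label (ICD10-block-like code, e.g. "E10-E14").
#' @param baseline_rate events per person-year at chron_age 0, delta 0 (> 0).
#' @param log_hr_age log hazard ratio per year of chronological age.
#' @param log_hr_delta log hazard ratio per year of latent acceleration.
#' @param prevalence_window_years years before baseline in which prevalent
#'   events may occur (>= 0).
#' @return a list of class \code{disease_spec}.
#' @export
disease_spec <- function(name, baseline_rate, log_hr_age = 0.0492,
                         log_hr_delta = 0.0492,
                         prevalence_window_years = 10) {
  if (baseline_rate <= 0) stopf("disease '%s': baseline_rate must be > 0", name)
  if (prevalence_window_years < 0)
    stopf("disease '%s': prevalence_window_years must be >= 0", name)
  structure(
    list(name = name, baseline_rate = baseline_rate,
         log_hr_age = log_hr_age, log_hr_delta = log_hr_delta,
         prevalence_window_years = prevalence_window_years),
    class = "disease_spec"
  )
}

default_assays <- function() {
  list(
    assay_spec("metabolite_panel", n_features = 30,
               age_loading_scale = 0.05, delta_loading_scale = 0.12,
               noise_sd = 1, batch_levels = 3),
    assay_spec("lipidomics", n_features = 60,
               age_loading_scale = 0.12, delta_loading_scale = 0.10,
               noise_sd = 1, batch_levels = 3),
    assay_spec("proteomics", n_features = 150,
               age_loading_scale = 0.25, delta_loading_scale = 0.10,
               noise_sd = 1, batch_levels = 4),
    assay_spec("methylation", n_features = 80,
               age_loading_scale = 0.35, delta_loading_scale = 0.08,
               noise_sd = 1, batch_levels = 2)
  )
}

default_risk_factors <- function() {
  list(
    risk_factor_spec("bmi", beta_age = 0.020, beta_delta = 0.030),
    risk_factor_spec("sbp", beta_age = 0.030, beta_delta = 0.020),
    risk_factor_spec("cortisol", beta_age = 0.012, beta_delta = 0.015),
    risk_factor_spec("creatinine", beta_age = 0.015, beta_delta = 0.020),
    risk_factor_spec("crp", beta_age = 0.015, beta_delta = 0.040),
    ## FEV1 declines with age: exercises the positive-effect screening gate
    risk_factor_spec("fev1", beta_age = -0.030, beta_delta = -0.020),
    risk_factor_spec("total_cholesterol", beta_age = 0.018, beta_delta = 0.020)
  )
}

default_diseases <- function() {
  list(
    disease_spec("C00-C97", baseline_rate = 3e-4),
    disease_spec("E10-E14", baseline_rate = 5e-4),
    disease_spec("I10-I15", baseline_rate = 8e-4),
    disease_spec("J09-J18", baseline_rate = 5e-4)
  )
}

#' Configure a synthetic cohort simulation
#'
#' Defaults describe the study conditions the package's analyses are
#' exercised under: 1500 individuals aged 16-100, latent acceleration SD of
#' 5 years, four assays spanning weak to strong age informativeness, seven
#' risk factors and four disease blocks followed for 10 years.
#'
#' @param n_individuals cohort size (>= 2).
#' @param age_range length-2 numeric, min < max, within [0, 120].
#' @param sigma_delta SD of the latent biological-age acceleration (years,
#'   >= 0).
#' @param assays list of \code{\link{assay_spec}} objects (non-empty).
#' @param risk_factors list of \code{\link{risk_factor_spec}} objects.
#' @param diseases list of \code{\link{disease_spec}} objects.
#' @param followup_years follow-up duration (> 0).
#' @param seed master seed; all stage seeds are derived from it (see
#'   \code{\link{derive_seed}}).
#' @return a list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_individuals = 1500,
                              age_range = c(16, 100),
                              sigma_delta = 5,
                              assays = default_assays(),
                              risk_factors = default_risk_factors(),
                              diseases = default_diseases(),
                              followup_years = 10,
                              seed = 1L) {
  if (n_individuals < 2) stopf("n_individuals must be >= 2")
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] < 0 || age_range[2] > 120)
    stopf("age_range must be (min, max) within [0, 120] with min < max")
  if (sigma_delta < 0) stopf("sigma_delta must be >= 0")
  if (length(assays) == 0) stopf("at least one assay must be configured")
  if (followup_years <= 0) stopf("followup_years must be > 0")
  for (a in assays) if (!inherits(a, "assay_spec"))
    stopf("assays must be assay_spec objects")
  for (d in diseases) if (!inherits(d, "disease_spec"))
    stopf("diseases must be disease_spec objects")
  structure(
    list(n_individuals = as.integer(n_individuals),
         age_range = as.numeric(age_range), sigma_delta = sigma_delta,
         assays = assays, risk_factors = risk_factors, diseases = diseases,
         followup_years = followup_years, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws chronological age uniformly over the configured range, a latent
#' biological-age acceleration \code{delta ~ N(0, sigma_delta^2)}, sex and
#' smoking status, one feature matrix per configured assay, risk factors,
#' and per-disease event records.  The same configuration (including seed)
#' always reproduces identical output.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list of class \code{ocaa_simulation} with elements
#'   \code{cohort} (data.frame: individual_id, chron_age, sex, smoking,
#'   assessment_time), \code{truth} (individual_id, delta — the latent
#'   acceleration, for tests and oracles only, never an input to the
#'   analysis), \code{omics} (named list of \code{\link{omics_matrix}}),
#'   \code{risk_factors} (data.frame), \code{disease} (data.frame of event
#'   records) and \code{config}.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stopf("config must be a simulation_config")
  n <- config$n_individuals
  ids <- sprintf("ind_%04d", seq_len(n))

  set.seed(derive_seed(config$seed, "cohort"))
  chron_age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- factor(ifelse(rbinom(n, 1, 0.5) == 1, "M", "F"), levels = c("F", "M"))
  smoking <- rbinom(n, 1, 0.2)
  cohort <- data.frame(
    individual_id = ids, chron_age = chron_age, sex = sex,
    smoking = smoking, assessment_time = 0,
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(config$seed, "delta"))
  delta <- if (config$sigma_delta > 0) rnorm(n, 0, config$sigma_delta)
           else rep(0, n)
  truth <- data.frame(individual_id = ids, delta = delta,
                      stringsAsFactors = FALSE)

  z_age <- as.numeric(scale(chron_age))
  z_delta <- if (sd(delta) > 0) as.numeric(scale(delta)) else rep(0, n)

  omics <- list()
  for (k in seq_along(config$assays)) {
    a <- config$assays[[k]]
    set.seed(derive_seed(config$seed, "assay", k))
    p <- a$n_features
    load_age <- abs(rnorm(p, 0, a$age_loading_scale))
    load_delta <- abs(rnorm(p, 0, a$delta_loading_scale))
    batch <- sample.int(a$batch_levels, n, replace = TRUE)
    batch_eff <- matrix(rnorm(p * a$batch_levels, 0, a$batch_sd),
                        nrow = a$batch_levels, ncol = p)
    x <- outer(z_age, load_age) + outer(z_delta, load_delta) +
      batch_eff[batch, , drop = FALSE] +
      matrix(rnorm(n * p, 0, a$noise_sd), n, p)
    dimnames(x) <- list(ids, sprintf("%s_f%03d", a$name, seq_len(p)))
    covars <- data.frame(sex = sex, smoking = smoking,
                         batch = factor(batch), row.names = ids)
    omics[[a$name]] <- omics_matrix(x, assay_name = a$name,
                                    covariates = covars)
  }

  rf <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (k in seq_along(config$risk_factors)) {
    r <- config$risk_factors[[k]]
    set.seed(derive_seed(config$seed, "risk_factor", k))
    rf[[r$name]] <- r$beta_age * chron_age + r$beta_delta * delta +
      rnorm(n, 0, r$noise_sd)
  }

  disease <- do.call(rbind, lapply(seq_along(config$diseases), function(k) {
    simulate_disease_times(
      cohort, truth, config$diseases[[k]],
      followup = config$followup_years,
      seed = derive_seed(config$seed, "disease", k)
    )
  }))
  if (is.null(disease))
    disease <- data.frame(individual_id = character(), disease_name = character(),
                          event_time = numeric(), event_flag = logical(),
                          prevalent_flag = logical(), censor_time = numeric(),
                          stringsAsFactors = FALSE)

  structure(
    list(cohort = cohort, truth = truth, omics = omics,
         risk_factors = rf, disease = disease, config = config),
    class = "ocaa_simulation"
  )
}

#' @export
print.ocaa_simulation <- function(x, ...) {
  cat(sprintf(
    "<ocaa_simulation: n=%d, ages %.1f-%.1f, %d assays, %d risk factors, %d diseases>\n",
    nrow(x$cohort), min(x$cohort$chron_age), max(x$cohort$chron_age),
    length(x$omics), length(x$config$risk_factors), length(x$config$diseases)
  ))
  invisible(x)
}

#' Simulate disease event records for one disease
#'
#' Incident event times are exponential with the individual-specific rate
#' \code{baseline_rate * exp(log_hr_age * chron_age + log_hr_delta * delta)}
#' and censored at \code{followup}.  Prevalent cases are generated by
#' running the same hazard backwards over the disease's prevalence window:
#' an individual is prevalent with the probability that an event under that
#' rate occurs within the window, and gets a negative event time.
#'
#' @param cohort cohort data.frame (needs individual_id, chron_age).
#' @param truth latent-truth data.frame (individual_id, delta).
#' @param spec a \code{\link{disease_spec}}.
#' @param followup follow-up duration in years (> 0).
#' @param seed integer seed.
#' @return data.frame with columns individual_id, disease_name, event_time
#'   (years since assessment, negative for prevalent events, NA when no
#'   event occurred), event_flag, prevalent_flag, censor_time.
#' @export
simulate_disease_times <- function(cohort, truth, spec, followup, seed) {
  if (!inherits(spec, "disease_spec")) stopf("spec must be a disease_spec")
  if (followup <= 0) stopf("followup must be > 0")
  delta <- truth$delta[match(cohort$individual_id, truth$individual_id)]
  rate <- spec$baseline_rate *
    exp(spec$log_hr_age * cohort$chron_age + spec$log_hr_delta * delta)

  set.seed(seed)
  t_inc <- rexp(nrow(cohort), rate)
  t_pre <- rexp(nrow(cohort), rate)

  prevalent <- t_pre < spec$prevalence_window_years
  incident <- !prevalent & t_inc <= followup
  event_time <- rep(NA_real_, nrow(cohort))
  event_time[prevalent] <- -t_pre[prevalent]
  event_time[incident] <- t_inc[incident]

  data.frame(
    individual_id = cohort$individual_id,
    disease_name = spec$name,
    event_time = event_time,
    event_flag = prevalent | incident,
    prevalent_flag = prevalent,
    censor_time = followup,
    stringsAsFactors = FALSE
  )
}

#' Expected incident event count under the generator's hazard
#'
#' Analytic companion to \code{\link{simulate_disease_times}}: for each
#' non-prevalent-eligible individual the probability of an incident event
#' within follow-up is \code{1 - exp(-rate * followup)}, conditional on not
#' being prevalent; the unconditional expected count sums
#' \code{exp(-rate * window) * (1 - exp(-rate * followup))}.
#'
#' @inheritParams simulate_disease_times
#' @return expected number of incident (non-prevalent) events.
#' @export
expected_incident_events <- function(cohort, truth, spec, followup) {
  delta <- truth$delta[match(cohort$individual_id, truth$individual_id)]
  rate <- spec$baseline_rate *
    exp(spec$log_hr_age * cohort$chron_age + spec$log_hr_delta * delta)
  sum(exp(-rate * spec$prevalence_window_years) * (1 - exp(-rate * followup)))
}

#' Construct an exact latent predictor bank
#'
#' Builds \code{p} predictors that are exactly mutually orthogonal in
#' sample, each with sample mean 0 and SD 1, whose sum is proportional to
#' standardised chronological age with no noise.  A clock that is the
#' projection of age onto any subset S of the bank then explains exactly
#' |S|/p of the variance in age, enabling machine-precision experiments on
#' the independent-sampling (ISLSP) null for clock overlap.
#'
#' The construction centres a Gaussian matrix, orthonormalises it by QR
#' decomposition, and rescales columns to unit sample SD, so exact
#' orthogonality holds in the realised sample, not just in expectation.
#'
#' @param n number of individuals (must exceed p + 1).
#' @param p number of latent predictors (>= 1).
#' @param seed integer seed.
#' @return list with \code{predictors} (n x p matrix) and \code{chron_age}
#'   (standardised age vector, equal to the row sums of the predictors
#'   rescaled to SD 1).
#' @export
simulate_latent_predictor_bank <- function(n, p, seed = 1L) {
  if (p < 1) stopf("p must be >= 1")
  if (n <= p + 1) stopf("n must exceed p + 1 for an exact construction")
  set.seed(seed)
  g <- matrix(rnorm(n * p), n, p)
  g <- sweep(g, 2, colMeans(g))            # columns orthogonal to intercept
  q <- qr.Q(qr(g))                          # orthonormal, still mean zero
  x <- q * sqrt(n - 1)                      # sample SD exactly 1
  colnames(x) <- sprintf("lp%03d", seq_len(p))
  z <- rowSums(x)
  list(predictors = x, chron_age = z / sd(z))
}
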