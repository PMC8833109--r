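# Shared fixtures, built once per test run.

# Small two-assay cohort used across module tests: one informative assay,
# one weak assay, plus risk factors and diseases at rates that give a
# workable number of events in a 400-person cohort.
small_config <- function(seed = 42L, n = 400L) {
  simulation_config(
    n_individuals = n,
    sigma_delta = 5,
    assays = list(
      assay_spec("strong", n_features = 60, age_loading_scale = 0.3,
                 delta_loading_scale = 0.1, noise_sd = 1, batch_levels = 2),
      assay_spec("weak", n_features = 30, age_loading_scale = 0.06,
                 delta_loading_scale = 0.12, noise_sd = 1, batch_levels = 2)
    ),
    diseases = list(
      disease_spec("E10-E14", baseline_rate = 2e-3),
      disease_spec("I10-I15", baseline_rate = 3e-3)
    ),
    followup_years = 10,
    seed = seed
  )
}

small_sim <- simulate_cohort(small_config())
small_age <- setNames(small_sim$cohort$chron_age,
                      small_sim$cohort$individual_id)
small_sex <- setNames(small_sim$cohort$sex, small_sim$cohort$individual_id)

# A bare cohort + latent truth without omics, for disease-time experiments
# at larger n.
bare_cohort <- function(n, seed, age_range = c(16, 100), sigma_delta = 5) {
  set.seed(seed)
  ids <- sprintf("p%05d", seq_len(n))
  list(
    cohort = data.frame(
      individual_id = ids,
      chron_age = runif(n, age_range[1], age_range[2]),
      sex = factor(sample(c("F", "M"), n, replace = TRUE),
                   levels = c("F", "M")),
      smoking = rbinom(n, 1, 0.2),
      assessment_time = 0,
      stringsAsFactors = FALSE
    ),
    truth = data.frame(individual_id = ids,
                       delta = rnorm(n, 0, sigma_delta),
                       stringsAsFactors = FALSE)
  )
}

# Feature matrix with one perfect age predictor among noise.
perfect_predictor_matrix <- function(age, n_noise = 20, seed = 1) {
  set.seed(seed)
  n <- length(age)
  x <- cbind(scale(age)[, 1],
             matrix(rnorm(n * n_noise), n, n_noise))
  dimnames(x) <- list(names(age), c("oracle", sprintf("noise%02d",
                                                      seq_len(n_noise))))
  x
}
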