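test_that("BH step-up, shrinkage, IVW and the sex test match closed forms", {
  # hand-computed step-up at q = 0.10: 0.04 <= 3/4 * 0.1
  expect_identical(bh_fdr(c(0.01, 0.02, 0.04, 0.9), q = 0.10),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(bh_fdr(rep(1e-10, 6))))
  expect_identical(bh_fdr(numeric(0)), logical(0))

  # conjugate posterior mean beta / (1 + se^2)
  expect_equal(shrink_beta(1, 1), 0.5)
  expect_equal(shrink_beta(2, 1e-8), 2, tolerance = 1e-10)
  expect_lt(abs(shrink_beta(3, 100)), 1e-3)

  # IVW: (1 / 1 + 3 / 4) / (1 + 1 / 4) = 1.4
  m <- ivw_mean(c(1, 3), c(1, 2))
  expect_equal(m$pooled_beta, 1.4)
  expect_equal(m$indicative_se, sqrt(1 / 1.25))
  expect_equal(ivw_mean(c(2, 4), c(3, 3))$pooled_beta, 3)  # equal ses: mean

  # sex difference z-test
  expect_equal(sex_difference_test(0.3, 0.1, 0.3, 0.2), 1)
  expect_equal(sex_difference_test(1.96 * sqrt(2), 1, 0, 1), 0.05,
               tolerance = 1e-3)
  expect_lt(sex_difference_test(5, 0.1, -5, 0.1), 1e-10)

  # enrichment counting on a constructed list
  res <- data.frame(outcome_type = "risk_factor", beta = c(1, 2, -1),
                    p_one_sided = c(0.01, 0.2, 0.5))
  e <- enrichment_summary(res)
  expect_equal(e$prop_positive, 2 / 3)
  expect_equal(e$prop_nominal, 1 / 3)

  # risk doubling horizon
  expect_equal(hazard_doubling_time(0.0492), log(2) / 0.0492)
  expect_error(hazard_doubling_time(-1), "positive")
})

test_that("chronAge screening recovers generator slopes and is calibrated under the null", {
  set.seed(201)
  n <- 1000
  age <- runif(n, 16, 100)
  sex <- factor(sample(c("F", "M"), n, TRUE))

  # slope recovery: 0.02 SD per year
  y <- 0.02 * age + rnorm(n)
  scr <- screen_chronage_risk_factor(y, age, sex, "toy")
  truth_std <- 0.02 / sd(y)
  expect_lt(abs(scr$chron_age_beta - truth_std), 2 * scr$se)

  # outcome equal to standardised age: beta = 1/SD(age), p -> 0
  scr2 <- screen_chronage_risk_factor(as.numeric(scale(age)), age, sex, "self")
  expect_equal(scr2$chron_age_beta, 1 / sd(age), tolerance = 1e-6)
  expect_lt(scr2$p_one_sided, 1e-100)

  # null calibration: one-sided p uniform over replicates
  set.seed(202)
  ps <- replicate(200, {
    yn <- rnorm(150)
    an <- runif(150, 16, 100)
    sn <- factor(sample(c("F", "M"), 150, TRUE))
    screen_chronage_risk_factor(yn, an, sn)$p_one_sided
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("outcome screening gates eligibility on sign, FDR and case counts", {
  sim <- small_sim
  scr <- screen_outcomes(sim$risk_factors, sim$disease, small_age, small_sex)
  expect_true(all(c("fdr_pass", "eligible") %in% names(scr)))
  # fev1 declines with age by construction: never eligible
  expect_false(scr$eligible[scr$outcome_name == "fev1"])
  # eligibility implies FDR pass and positive slope
  expect_true(all(scr$fdr_pass[scr$eligible]))
  expect_true(all(scr$chron_age_beta[scr$eligible] > 0))
  dz <- scr[scr$outcome_type == "disease", ]
  expect_true(all(dz$n_events[dz$eligible] > 5))
})

test_that("OCAA effects on risk factors recover the generator and honour the gate", {
  set.seed(210)
  n <- 1500
  age <- runif(n, 16, 100)
  sex <- factor(sample(c("F", "M"), n, TRUE))
  delta <- rnorm(n, 0, 5)
  # outcome with equal per-year effects of age and acceleration
  a <- 0.03
  y <- a * age + a * delta + rnorm(n)
  scr <- screen_chronage_risk_factor(y, age, sex, "toy")

  res <- associate_ocaa_risk_factor(y, delta, age, sex,
                                    chron_age_beta = scr$chron_age_beta,
                                    clock_name = "oracle", outcome_name = "toy")
  # a year of (noise-free) OCAA is as deleterious as a year of chronAge
  se_rescaled <- res$se / abs(scr$chron_age_beta)
  expect_lt(abs(res$rescaled_beta - 1), 2 * se_rescaled)

  # independent-noise OCAA: null effect
  res0 <- associate_ocaa_risk_factor(y, rnorm(n, 0, 5), age, sex,
                                     chron_age_beta = scr$chron_age_beta)
  expect_lt(abs(res0$beta), 2 * res0$se)

  # standardising OCAA rescales beta but leaves the z-statistic unchanged
  res_std <- associate_ocaa_risk_factor(y, as.numeric(scale(delta)), age, sex,
                                        chron_age_beta = scr$chron_age_beta)
  expect_equal(res_std$beta / res_std$se, res$beta / res$se, tolerance = 1e-8)
  expect_equal(res_std$beta, res$beta * sd(delta), tolerance = 1e-6)
})

test_that("OCAA effects on disease recover the generator ratio and attenuate with noise", {
  bc <- bare_cohort(8000, seed = 220)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)
  sex <- setNames(bc$cohort$sex, bc$cohort$individual_id)
  delta <- setNames(bc$truth$delta, bc$truth$individual_id)
  spec <- disease_spec("E10-E14", baseline_rate = 2e-3,
                       log_hr_age = 0.0492, log_hr_delta = 0.0492)
  rec <- simulate_disease_times(bc$cohort, bc$truth, spec, followup = 10,
                                seed = 221)

  # oracle clock (OCAA = delta exactly): rescaled effect ~ 1
  res <- associate_ocaa_disease(rec, delta, age, sex,
                                pooled_divisor = 0.0492,
                                clock_name = "oracle")
  expect_lt(abs(res$rescaled_beta - 1), 2 * res$se / 0.0492)

  # null acceleration effect
  spec0 <- disease_spec("I10-I15", baseline_rate = 2e-3,
                        log_hr_age = 0.0492, log_hr_delta = 0)
  rec0 <- simulate_disease_times(bc$cohort, bc$truth, spec0, followup = 10,
                                 seed = 222)
  res0 <- associate_ocaa_disease(rec0, delta, age, sex,
                                 pooled_divisor = 0.0492)
  expect_lt(abs(res0$rescaled_beta), 2 * res0$se / 0.0492)

  # attenuation: measurement noise on the clock pulls the effect towards 0
  set.seed(223)
  betas <- vapply(c(0, 5, 15), function(ns) {
    noisy <- delta + rnorm(length(delta), 0, ns)
    associate_ocaa_disease(rec, noisy, age, sex,
                           pooled_divisor = 0.0492)$rescaled_beta
  }, numeric(1))
  expect_true(all(diff(betas) < 0))
  expect_gt(betas[1], betas[3] + 0.2)
})

test_that("associate_all tests only eligible outcomes and honours exclusions", {
  sim <- small_sim
  scr <- screen_outcomes(sim$risk_factors, sim$disease, small_age, small_sex)
  q <- qc_pipeline(sim$omics$strong,
                   qc_config(covariate_names = c("sex", "batch")))
  fit <- omics_clock(q, small_age, seed = 12)
  ages <- clock_age_table(fit, q, small_age, clock_name = "strong")

  excl <- data.frame(clock_name = "strong", outcome_name = "bmi",
                     stringsAsFactors = FALSE)
  res <- associate_all(ages, scr, sim$risk_factors, sim$disease,
                       small_age, small_sex, exclusions = excl)
  eligible <- scr$outcome_name[scr$eligible]
  expect_true(all(res$outcome_name %in% setdiff(eligible, "bmi")))
  expect_false("bmi" %in% res$outcome_name)
  expect_false("fev1" %in% res$outcome_name)
  expect_true(all(c("rescaled_beta", "shrunk_beta", "fdr_pass") %in%
                    names(res)))
  # smoking-adjusted variant runs and keeps the same test grid
  smoking <- setNames(sim$cohort$smoking, sim$cohort$individual_id)
  res_smk <- associate_all(ages, scr, sim$risk_factors, sim$disease,
                           small_age, small_sex, exclusions = excl,
                           smoking = smoking)
  expect_identical(res_smk$outcome_name, res$outcome_name)
})

test_that("BH at q = 0.10 controls the false-discovery proportion under a null generator", {
  # fully null OCAA effects: risk factors depend on age only, clock is noise
  set.seed(230)
  fdp <- replicate(50, {
    n <- 300
    age <- runif(n, 16, 100)
    sex <- factor(sample(c("F", "M"), n, TRUE))
    ocaa <- rnorm(n, 0, 5)
    ps <- vapply(1:7, function(j) {
      y <- 0.02 * age + rnorm(n)
      associate_ocaa_risk_factor(y, ocaa, age, sex,
                                 chron_age_beta = 0.02)$p_one_sided
    }, numeric(1))
    mean(bh_fdr(ps, q = 0.10))  # all discoveries are false here
  })
  expect_lte(mean(fdp), 0.15)
})

test_that("sex-consistency assessment counts sign agreement on strong effects", {
  bc <- bare_cohort(6000, seed = 240)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)
  sex <- setNames(bc$cohort$sex, bc$cohort$individual_id)
  delta <- setNames(bc$truth$delta, bc$truth$individual_id)
  spec <- disease_spec("E10-E14", baseline_rate = 3e-3,
                       log_hr_age = 0.05, log_hr_delta = 0.08)
  rec <- simulate_disease_times(bc$cohort, bc$truth, spec, followup = 10,
                                seed = 241)
  pooled <- as.data.frame(
    unclass(associate_ocaa_disease(rec, delta, age, sex,
                                   clock_name = "oracle")),
    stringsAsFactors = FALSE
  )
  ages <- data.frame(individual_id = names(delta), clock_name = "oracle",
                     ocaa = unname(delta), stringsAsFactors = FALSE)
  out <- sex_sign_consistency(pooled, ages, rec, age, sex)
  expect_equal(out$n_assessed, 1L)
  expect_equal(out$prop_consistent, 1)
  expect_true(all(out$detail$p_difference >= 0 & out$detail$p_difference <= 1))
})
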