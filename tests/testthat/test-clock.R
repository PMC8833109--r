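test_that("cohort splitting honours sizes, completeness preference and seeds", {
  ids <- sprintf("i%04d", 1:1000)
  sp <- split_cohort(ids, fraction = 0.75, seed = 1)
  expect_length(sp$test_ids, 250)
  expect_length(sp$train_ids, 750)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)

  # preference saturates: all test slots filled from the complete pool
  complete <- ids[1:300]
  sp2 <- split_cohort(ids, complete_ids = complete, seed = 2)
  expect_true(all(sp2$test_ids %in% complete))

  # too-small complete pool: topped up from the rest
  sp3 <- split_cohort(ids, complete_ids = ids[1:100], seed = 3)
  expect_true(all(ids[1:100] %in% sp3$test_ids))
  expect_length(sp3$test_ids, 250)

  expect_identical(split_cohort(ids, seed = 9), split_cohort(ids, seed = 9))
  expect_error(split_cohort(ids, fraction = 1.2), "fraction")
})

test_that("a perfect predictor survives penalisation; pure noise does not fake accuracy", {
  bc <- bare_cohort(1000, seed = 21)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)

  x <- perfect_predictor_matrix(age, n_noise = 20, seed = 4)
  fit <- omics_clock(x, age, seed = 11, assay_name = "oracle_assay")
  expect_gt(fit$test_r, 0.99)
  expect_true("oracle" %in% names(fit$coefficients))

  # pure noise: test-set correlation stays inside the null envelope
  for (s in c(1, 2)) {
    set.seed(s)
    noise <- matrix(rnorm(1000 * 50), 1000, 50,
                    dimnames = list(names(age), sprintf("n%02d", 1:50)))
    fitn <- suppressWarnings(omics_clock(noise, age, seed = s))
    expect_lt(abs(ifelse(is.na(fitn$test_r), 0, fitn$test_r)), 0.15)
  }
})

test_that("prediction is internally consistent and row-exchangeable", {
  bc <- bare_cohort(600, seed = 5)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)
  x <- perfect_predictor_matrix(age, n_noise = 10, seed = 6)
  fit <- omics_clock(x, age, seed = 3)

  # training-set prediction reproduces the stored train_r
  oca_tr <- predict(fit, x[fit$train_ids, ])
  expect_equal(cor(oca_tr, age[fit$train_ids]), fit$train_r,
               tolerance = 1e-12)

  # row-permuted input gives row-permuted output
  perm <- sample(rownames(x))
  expect_equal(predict(fit, x[perm, ]), predict(fit, x)[perm],
               tolerance = 1e-12)

  # absent model features are named in the error
  expect_error(predict(fit, x[, setdiff(colnames(x), "oracle")]), "oracle")

  # missing feature value -> missing estimated age
  x2 <- x
  x2[3, "oracle"] <- NA
  expect_true(is.na(predict(fit, x2)[3]))
})

test_that("age acceleration arithmetic and tabulation are exact", {
  expect_equal(compute_ocaa(c(50, 60), c(45, 60)), c(5, 0))
  expect_error(compute_ocaa(1:3, 1:2), "lengths differ")

  bc <- bare_cohort(600, seed = 8)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)
  x <- perfect_predictor_matrix(age, n_noise = 10, seed = 9)
  fit <- omics_clock(x, age, seed = 2)
  tab <- clock_age_table(fit, x, age)
  expect_equal(tab$ocaa, tab$oca - age[tab$individual_id],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(mean(tab$ocaa_std), 0, tolerance = 1e-12)
  expect_equal(sd(tab$ocaa_std), 1, tolerance = 1e-12)
  # unbiased synthetic data: mean test-set OCAA within 2 SE of zero
  expect_lt(abs(mean(tab$ocaa)), 2 * sd(tab$ocaa) / sqrt(nrow(tab)))
})

test_that("trained-clock OCAA tracks the latent acceleration when it loads on features", {
  cfg <- simulation_config(
    n_individuals = 800,
    assays = list(assay_spec("deltaassay", 60, age_loading_scale = 0.15,
                             delta_loading_scale = 0.25, batch_levels = 1)),
    seed = 77L
  )
  sim <- simulate_cohort(cfg)
  age <- setNames(sim$cohort$chron_age, sim$cohort$individual_id)
  q <- qc_pipeline(sim$omics$deltaassay, qc_config(covariate_names = "sex"))
  fit <- omics_clock(q, age, seed = 17)
  tab <- clock_age_table(fit, q, age)  # held-out test set
  delta <- setNames(sim$truth$delta, sim$truth$individual_id)
  ct <- cor.test(tab$ocaa, delta[tab$individual_id], alternative = "greater")
  expect_lt(ct$p.value, 0.01)
})

test_that("stability selection keeps perfect predictors and drops pure noise", {
  bc <- bare_cohort(500, seed = 30)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)
  x <- perfect_predictor_matrix(age, n_noise = 30, seed = 12)
  st <- stability_select(x, age, iterations = 20, threshold = 0.95, seed = 3)
  expect_equal(unname(st$frequency["oracle"]), 1.0)
  expect_true("oracle" %in% st$core_features)
  expect_gt(st$core_clock$test_r, 0.99)

  # pure noise: no feature reaches the 95% threshold
  set.seed(44)
  noise <- matrix(rnorm(500 * 60), 500, 60,
                  dimnames = list(names(age), sprintf("n%02d", 1:60)))
  expect_error(
    suppressWarnings(stability_select(noise, age, iterations = 15, seed = 5)),
    "lower threshold"
  )
})

test_that("mega-omics merge aligns individuals and keeps feature provenance", {
  sim <- small_sim
  mats <- lapply(sim$omics, function(a)
    qc_pipeline(a, qc_config(covariate_names = c("sex", "batch"))))
  mega <- build_mega_matrix(mats)
  shared <- Reduce(intersect, lapply(mats, function(m) rownames(m$values)))
  expect_equal(nrow(mega$values), length(shared))
  expect_equal(ncol(mega$values), sum(vapply(mats, function(m)
    ncol(m$values), numeric(1))))
  expect_true(all(grepl("^(strong|weak)\\.", colnames(mega$values))))

  # single assay: identity
  expect_identical(build_mega_matrix(mats[1]), mats[[1]])

  # duplicate ids after prefixing are refused
  dup <- mats
  dup$strong2 <- mats$strong
  dup$strong2$assay_name <- "strong"
  expect_error(build_mega_matrix(dup), "duplicate")

  age <- small_age
  fit <- omics_clock(mega, age, seed = 23)
  shares <- mega_feature_shares(fit)
  expect_true(all(names(shares) %in% c("strong", "weak")))
  expect_equal(sum(shares), 1, tolerance = 1e-12)
})

test_that("principal-component clocks train on projected scores without leakage", {
  bc <- bare_cohort(700, seed = 50)
  age <- setNames(bc$cohort$chron_age, bc$cohort$individual_id)
  # age-dominated first PC: several correlated age-loaded features
  set.seed(51)
  z <- scale(age)[, 1]
  x <- sapply(1:20, function(j) 0.9 * z + rnorm(700, 0, 0.5))
  dimnames(x) <- list(names(age), sprintf("f%02d", 1:20))

  full <- omics_clock(x, age, seed = 7)
  pc3 <- pc_clock(x, 3, age, train_ids = full$train_ids,
                  test_ids = full$test_ids, seed = 7)
  expect_lt(abs(pc3$test_r - full$test_r), 0.1)

  # predict from the original feature space matches the stored test_r
  oca <- predict(pc3, x[pc3$test_ids, ])
  expect_equal(cor(oca, age[pc3$test_ids]), pc3$test_r, tolerance = 1e-10)

  expect_error(pc_clock(x, 21, age, seed = 1), "rank")

  # one noise component: null envelope
  set.seed(52)
  noise <- matrix(rnorm(700 * 15), 700, 15,
                  dimnames = list(names(age), sprintf("n%02d", 1:15)))
  pcn <- suppressWarnings(pc_clock(noise, 1, age, seed = 8))
  expect_lt(abs(ifelse(is.na(pcn$test_r), 0, pcn$test_r)), 0.15)
})
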