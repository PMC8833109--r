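test_that("expected overlap follows the independence formula", {
  expect_equal(expected_overlap(0.5, 0.5), 0.75)
  expect_equal(expected_overlap(0, 0.3), 0.3)
  expect_equal(expected_overlap(1, 0.3), 1)
  expect_equal(expected_overlap(0.2, 0.4), 1 - 0.8 * 0.6)
  expect_error(expected_overlap(-0.1, 0.5), "must be in")
})

test_that("scaled excess overlap hits its landmark values and properties", {
  # a clock against itself scores exactly 1, whatever its accuracy
  for (v in c(0.1, 0.25, 0.5, 0.9, 0.99)) {
    expect_equal(excess_overlap(v, v, O = v), 1)
  }

  # worked example: E = 0.8, E_min = 0.6 -> (0.8 - 0.7) / 0.2 = 0.5
  expect_equal(excess_overlap(0.6, 0.5, 0.7), 0.5)

  # independence expectation scores 0
  expect_equal(excess_overlap(0.5, 0.5, 0.75), 0)

  # fully complementary clocks score negative
  expect_lt(excess_overlap(0.5, 0.4, O = 0.9), 0)

  # strictly decreasing in O over (E_min, E_max]
  Os <- seq(0.601, 0.9, length.out = 20)
  vals <- vapply(Os, function(o) excess_overlap(0.6, 0.3, o), numeric(1))
  expect_true(all(diff(vals) < 0))

  # symmetry in the clock labels
  expect_equal(excess_overlap(0.3, 0.6, 0.65), excess_overlap(0.6, 0.3, 0.65))

  # degenerate scale (one clock explains nothing): NA with warning
  expect_warning(out <- excess_overlap(0.5, 0, 0.5), "degenerate")
  expect_true(is.na(out))

  # O outside the attainable range is clamped with a warning
  expect_warning(out <- excess_overlap(0.5, 0.4, 0.45), "clamped")
  expect_equal(out, 1)  # clamped to E_min -> full redundancy
})

test_that("unique variances match the part-correlation oracle on random instances", {
  # oracle: squared part correlation = cor(y, residual of x_i on the others)^2,
  # an independent route to the same quantity as the leave-one-out R^2 drop
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(3:5, 1)
    n <- 80
    z <- rnorm(n)
    x <- sapply(seq_len(k), function(j) 0.7 * z + rnorm(n))
    y <- z + rnorm(n, 0, 0.5)
    colnames(x) <- sprintf("c%d", seq_len(k))
    sr2 <- unique_variance(y, as.data.frame(x))
    oracle <- vapply(seq_len(k), function(i) {
      r <- resid(lm(x[, i] ~ x[, -i, drop = FALSE]))
      cor(y, r)^2
    }, numeric(1))
    expect_equal(unname(sr2), oracle, tolerance = 1e-8)
  }
})

test_that("unique variance handles identical and orthogonal clocks exactly", {
  b <- simulate_latent_predictor_bank(120, 60, seed = 9)
  y <- b$chron_age
  # exactly orthogonal subset-sum clocks
  c1 <- rowSums(b$predictors[, 1:20])
  c2 <- rowSums(b$predictors[, 21:40])
  c3 <- rowSums(b$predictors[, 41:60])
  sr2 <- unique_variance(y, list(a = c1, b = c2, c = c3))
  # orthogonality: each unique variance equals the univariate R^2 = 20/60
  expect_equal(unname(sr2), rep(1 / 3, 3), tolerance = 1e-10)

  # identical clocks contribute no unique variance
  expect_warning(sr2id <- unique_variance(y, list(a = c1, b = c1)),
                 "collinear")
  expect_equal(unname(sr2id), c(0, 0), tolerance = 1e-10)

  expect_error(unique_variance(y, list(a = c1)), "at least two")
})

test_that("variance partition conserves its components and nails exact cases", {
  set.seed(11)
  # conservation on random instances
  for (rep in 1:20) {
    n <- 60 + rep
    z <- rnorm(n)
    k <- sample(2:5, 1)
    x <- as.data.frame(sapply(seq_len(k), function(j) 0.6 * z + rnorm(n)))
    names(x) <- sprintf("c%d", seq_len(k))
    y <- z + rnorm(n)
    p <- partition_variance(y, x)
    expect_lt(abs(sum(p$unique) + p$shared + p$unexplained - 1), 1e-9)
    expect_true(all(c(p$unique, p$shared, p$unexplained) >= -1e-9))
  }

  # k identical clocks with univariate R^2 = v: unique 0, shared v
  b <- simulate_latent_predictor_bank(100, 50, seed = 4)
  y <- b$chron_age
  ck <- rowSums(b$predictors[, 1:25])  # v = 0.5 exactly
  p <- suppressWarnings(partition_variance(y, list(a = ck, b = ck, c = ck)))
  expect_equal(unname(p$unique), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(p$shared, 0.5, tolerance = 1e-9)
  expect_equal(p$unexplained, 0.5, tolerance = 1e-9)

  # pairwise: orthogonal clocks share nothing
  c1 <- rowSums(b$predictors[, 1:25])
  c2 <- rowSums(b$predictors[, 26:50])
  pp <- pairwise_partition(y, c1, c2)
  expect_equal(pp$shared, 0, tolerance = 1e-9)
  expect_equal(unname(pp$unique), c(0.5, 0.5), tolerance = 1e-9)

  expect_error(partition_variance(rnorm(4), list(a = rnorm(4), b = rnorm(4),
                                                 c = rnorm(4))),
               "too (few|small)")
})

test_that("bivariate overlap statistics agree with direct regression", {
  set.seed(21)
  n <- 500
  z <- rnorm(n)
  o1 <- 0.8 * z + rnorm(n)
  o2 <- 0.5 * z + rnorm(n)
  y <- z + rnorm(n, 0, 0.5)
  ov <- overlap_pair(y, o1, o2)
  expect_equal(ov$v1, summary(lm(y ~ o1))$r.squared, tolerance = 1e-12)
  expect_equal(ov$v2, summary(lm(y ~ o2))$r.squared, tolerance = 1e-12)
  expect_equal(ov$O, summary(lm(y ~ o1 + o2))$r.squared, tolerance = 1e-12)
  expect_equal(ov$E, 1 - (1 - ov$v1) * (1 - ov$v2))
  expect_equal(ov$E_min, max(ov$v1, ov$v2))
  expect_equal(ov$excess, (ov$E - ov$O) / (ov$E - ov$E_min))
})

test_that("clock overlap matrices are symmetric with unit diagonal and exclude mega clocks", {
  set.seed(31)
  n <- 300
  z <- rnorm(n)
  ocas <- data.frame(
    a = 0.9 * z + rnorm(n), b = 0.7 * z + rnorm(n),
    c = 0.4 * z + rnorm(n), mega_omics = 0.95 * z + rnorm(n, 0, 0.3)
  )
  y <- z + rnorm(n, 0, 0.4)
  om <- clock_overlap_matrix(y, ocas)
  expect_identical(colnames(om$excess), c("a", "b", "c"))  # mega excluded
  expect_equal(om$excess, t(om$excess))
  expect_equal(unname(diag(om$excess)), rep(1, 3))
  expect_equal(dim(om$ocaa_cor), c(3L, 3L))
  expect_setequal(om$order, c("a", "b", "c"))
  expect_equal(nrow(om$pairs), 3)

  # keeping the mega clock is possible but explicit
  om2 <- clock_overlap_matrix(y, ocas, exclude = character())
  expect_equal(ncol(om2$excess), 4L)
})

test_that("ISLSP constructions give zero excess at expected overlap, in mean and exactly", {
  b <- simulate_latent_predictor_bank(150, 100, seed = 3)
  ov <- islsp_overlap(b, 1:50, 26:75)
  expect_equal(ov$v1, 0.5, tolerance = 1e-10)
  expect_equal(ov$v2, 0.5, tolerance = 1e-10)
  expect_equal(ov$O, 0.75, tolerance = 1e-10)
  expect_equal(ov$excess, 0, tolerance = 1e-9)

  # disjoint halves: the union explains everything (maximum-overlap bound)
  ov2 <- islsp_overlap(b, 1:50, 51:100)
  expect_equal(ov2$O, 1, tolerance = 1e-10)
  expect_equal(ov2$O, ov2$v1 + ov2$v2, tolerance = 1e-10)

  mc <- islsp_monte_carlo(b, 50, 50, n_draws = 100, seed = 17)
  expect_lt(abs(mean(mc)), 0.05)

  expect_error(islsp_overlap(b, integer(0), 1:3), "non-empty")
  expect_error(islsp_overlap(b, 1:5, 99:105), "indices")
})
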