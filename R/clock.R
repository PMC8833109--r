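## ---------------------------------------------------------------------------
## Elastic-net ageing clocks.  omics_clock() is the central fitting
## function; it returns a classed object with coef/predict/print/summary/
## residuals/plot methods.  Features are standardised with training-set
## statistics only (stored in the model) so test individuals never leak
## into the scaling.
## ---------------------------------------------------------------------------

#' Split a cohort into training and testing sets
#'
#' Draws \code{round((1 - fraction) * n)} test individuals, preferentially
#' from the pool with complete data on every assay when
#' \code{complete_ids} is given, then fills any remainder from the rest.
#' Train and test are disjoint and exhaustive.
#'
#' @param ids character vector of individual ids.
#' @param fraction training fraction in (0, 1) (default 0.75).
#' @param complete_ids optional ids with complete omics, preferred for the
#'   test set so every clock can be evaluated on the same individuals.
#' @param seed integer seed.
#' @return list with \code{train_ids} and \code{test_ids}.
#' @export
split_cohort <- function(ids, fraction = 0.75, complete_ids = NULL, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  n_test <- round((1 - fraction) * length(ids))
  set.seed(seed)
  pool <- if (is.null(complete_ids)) character() else intersect(ids, complete_ids)
  test <- if (length(pool) >= n_test) {
    sample(pool, n_test)
  } else {
    rest <- sample(setdiff(ids, pool), n_test - length(pool))
    c(pool, rest)
  }
  list(train_ids = setdiff(ids, test), test_ids = test)
}

clock_values <- function(x) {
  if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
}

align_age <- function(chron_age, ids) {
  if (!is.null(names(chron_age))) {
    missing <- setdiff(ids, names(chron_age))
    if (length(missing))
      stopf("chron_age missing for %d individuals", length(missing))
    chron_age[ids]
  } else {
    stopf("chron_age must be named by individual id")
  }
}

#' Fit an elastic-net ageing clock
#'
#' Penalised least-squares regression of chronological age on the assay's
#' features.  The penalty strength lambda is chosen by k-fold
#' cross-validation in the training set at minimum mean squared error.
#' Three penalisation methods are available: elastic net at a fixed
#' mixing alpha (default 0.5), the LASSO (alpha = 1), and elastic net with
#' alpha itself chosen by cross-validation over a grid.  Individuals with
#' any missing feature in this assay are excluded from training, and
#' receive a missing estimated age from \code{predict}.
#'
#' @param x an \code{\link{omics_matrix}} (QC'd and standardised) or a
#'   numeric matrix with individual row names and feature column names.
#' @param chron_age numeric vector of ages, named by individual id.
#' @param train_ids,test_ids id vectors; when \code{NULL} a fresh 75/25
#'   split of the complete-case individuals is drawn with \code{seed}.
#' @param alpha elastic-net mixing parameter (ignored for
#'   \code{method = "lasso"} or \code{"cv_alpha"}).
#' @param method one of \code{"enet"} (fixed alpha), \code{"lasso"},
#'   \code{"cv_alpha"}.
#' @param nfolds cross-validation folds (default 10).
#' @param seed integer seed for the split and the fold assignment.
#' @param assay_name label stored in the model.
#' @return an object of class \code{omics_clock}: intercept, sparse
#'   coefficients (years per SD of feature), chosen alpha and lambda,
#'   training-set feature centres/scales, train/test ids and the
#'   correlation of estimated with chronological age in both sets.
#' @export
omics_clock <- function(x, chron_age, train_ids = NULL, test_ids = NULL,
                        alpha = 0.5, method = c("enet", "lasso", "cv_alpha"),
                        nfolds = 10, seed = 1L, assay_name = NULL) {
  method <- match.arg(method)
  v <- clock_values(x)
  assay_name <- assay_name %||%
    (if (inherits(x, "omics_matrix")) x$assay_name else "assay")

  complete <- rownames(v)[complete.cases(v)]
  if (is.null(train_ids)) {
    sp <- split_cohort(complete, fraction = 0.75, seed = derive_seed(seed, "split"))
    train_ids <- sp$train_ids
    test_ids <- sp$test_ids
  }
  train_ids <- intersect(train_ids, complete)
  if (is.null(test_ids)) test_ids <- setdiff(complete, train_ids)
  if (length(train_ids) < 2 * nfolds)
    stopf("assay '%s': %d complete training rows is fewer than 2 x %d folds",
          assay_name, length(train_ids), nfolds)

  xt <- v[train_ids, , drop = FALSE]
  y <- as.numeric(align_age(chron_age, train_ids))

  centre <- colMeans(xt)
  scl <- apply(xt, 2, sd)
  usable <- scl > 0
  if (!any(usable)) stopf("assay '%s': no non-constant features", assay_name)
  xt <- sweep(sweep(xt[, usable, drop = FALSE], 2, centre[usable]), 2,
              scl[usable], "/")

  set.seed(derive_seed(seed, "folds"))
  foldid <- sample(rep_len(seq_len(nfolds), nrow(xt)))

  if (ncol(xt) == 1) {
    ## a single feature needs no penalisation
    fit <- stats::lm.fit(cbind(1, xt), y)
    intercept <- fit$coefficients[1]
    beta <- setNames(fit$coefficients[2], colnames(xt))
    alpha_used <- alpha
    lambda <- 0
  } else if (method == "cv_alpha") {
    grid <- seq(0.1, 1, by = 0.1)
    cvs <- lapply(grid, function(a)
      glmnet::cv.glmnet(xt, y, alpha = a, foldid = foldid))
    best <- which.min(vapply(cvs, function(cv) min(cv$cvm), numeric(1)))
    cv <- cvs[[best]]
    alpha_used <- grid[best]
    lambda <- cv$lambda.min
    cf <- as.matrix(coef(cv, s = "lambda.min"))
    intercept <- cf[1, 1]
    beta <- cf[-1, 1]
  } else {
    alpha_used <- if (method == "lasso") 1 else alpha
    cv <- glmnet::cv.glmnet(xt, y, alpha = alpha_used, foldid = foldid)
    lambda <- cv$lambda.min
    cf <- as.matrix(coef(cv, s = "lambda.min"))
    intercept <- cf[1, 1]
    beta <- cf[-1, 1]
  }

  beta <- beta[beta != 0]
  if (length(beta) == 0)
    warnf("assay '%s': all coefficients shrunk to zero", assay_name)

  model <- structure(
    list(assay_name = assay_name, method = method, alpha = alpha_used,
         lambda = lambda, intercept = unname(intercept), coefficients = beta,
         feature_center = centre[usable], feature_scale = scl[usable],
         train_ids = train_ids, test_ids = test_ids, seed = seed),
    class = "omics_clock"
  )

  oca_train <- predict(model, v[train_ids, , drop = FALSE])
  model$train_r <- safe_cor(oca_train, align_age(chron_age, train_ids))
  if (length(test_ids)) {
    keep <- intersect(test_ids, rownames(v))
    oca_test <- predict(model, v[keep, , drop = FALSE])
    model$test_r <- safe_cor(oca_test, align_age(chron_age, keep))
  } else {
    model$test_r <- NA_real_
  }
  model
}

safe_cor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Estimate ages from a fitted clock
#'
#' Applies the stored training-set centring/scaling and the sparse
#' coefficient vector.  Individuals with a missing value in any feature the
#' model uses receive \code{NA}.
#'
#' @param object an \code{omics_clock}.
#' @param newdata an \code{\link{omics_matrix}} or numeric matrix carrying
#'   at least the model's features.
#' @param ... unused.
#' @return named numeric vector of estimated ages (OCA).
#' @export
predict.omics_clock <- function(object, newdata, ...) {
  v <- clock_values(newdata)
  feats <- names(object$coefficients)
  absent <- setdiff(feats, colnames(v))
  if (length(absent))
    stopf("clock '%s': features absent from data: %s", object$assay_name,
          paste(head(absent, 5), collapse = ", "))
  if (length(feats) == 0)
    return(setNames(rep(object$intercept, nrow(v)), rownames(v)))
  xs <- sweep(sweep(v[, feats, drop = FALSE], 2, object$feature_center[feats]),
              2, object$feature_scale[feats], "/")
  setNames(object$intercept + as.numeric(xs %*% object$coefficients),
           rownames(v))
}

#' @export
coef.omics_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.omics_clock <- function(x, ...) {
  cat(sprintf(
    "<omics_clock '%s': %d features selected, alpha=%.2f, lambda=%.4g>\n",
    x$assay_name, length(x$coefficients), x$alpha, x$lambda
  ))
  cat(sprintf("  train r = %.3f (n=%d), test r = %.3f (n=%d)\n",
              x$train_r, length(x$train_ids), x$test_r, length(x$test_ids)))
  invisible(x)
}

#' @export
summary.omics_clock <- function(object, ...) {
  out <- list(
    assay_name = object$assay_name, method = object$method,
    alpha = object$alpha, lambda = object$lambda,
    n_selected = length(object$coefficients),
    n_train = length(object$train_ids), n_test = length(object$test_ids),
    train_r = object$train_r, test_r = object$test_r,
    top_features = head(sort(abs(object$coefficients), decreasing = TRUE), 10)
  )
  class(out) <- "summary.omics_clock"
  out
}

#' @export
print.summary.omics_clock <- function(x, ...) {
  cat(sprintf("Ageing clock for assay '%s' (%s, alpha=%.2f)\n",
              x$assay_name, x$method, x$alpha))
  cat(sprintf("  lambda = %.4g, %d features selected\n", x$lambda, x$n_selected))
  cat(sprintf("  chronAge correlation: train %.3f (n=%d), test %.3f (n=%d)\n",
              x$train_r, x$n_train, x$test_r, x$n_test))
  cat("  largest |coefficients| (years per SD):\n")
  print(round(x$top_features, 3))
  invisible(x)
}

#' Residuals of an ageing clock are age accelerations
#'
#' @param object an \code{omics_clock}.
#' @param newdata data to predict on (defaults must be supplied by caller).
#' @param chron_age named age vector.
#' @param ... unused.
#' @return named OCAA vector (estimated minus chronological age).
#' @export
residuals.omics_clock <- function(object, newdata, chron_age, ...) {
  oca <- predict(object, newdata)
  compute_ocaa(oca, align_age(chron_age, names(oca)))
}

#' @export
plot.omics_clock <- function(x, newdata, chron_age, ...) {
  oca <- predict(x, newdata)
  age <- align_age(chron_age, names(oca))
  graphics::plot(age, oca, xlab = "chronological age (years)",
                 ylab = "estimated age (years)",
                 main = sprintf("%s clock (r = %.2f)", x$assay_name,
                                safe_cor(oca, age)), ...)
  graphics::abline(0, 1)
  invisible(x)
}

#' Omics clock age acceleration
#'
#' OCAA is the excess of the clock's estimated age over chronological age,
#' in years.
#'
#' @param oca estimated ages.
#' @param chron_age chronological ages (same order/length).
#' @return \code{oca - chron_age}.
#' @export
compute_ocaa <- function(oca, chron_age) {
  if (length(oca) != length(chron_age))
    stopf("oca and chron_age lengths differ")
  oca - chron_age
}

#' Tabulate estimated ages and accelerations for one clock
#'
#' @param clock an \code{omics_clock} (or any object with a
#'   \code{predict} method returning named ages).
#' @param x data to evaluate on.
#' @param chron_age named age vector.
#' @param ids individuals to evaluate (default: the clock's test set).
#' @param clock_name label (default: the assay name).
#' @return data.frame with individual_id, clock_name, oca, ocaa and
#'   ocaa_std (ocaa standardised over the evaluated individuals).
#' @export
clock_age_table <- function(clock, x, chron_age, ids = clock$test_ids,
                            clock_name = clock$assay_name) {
  v <- clock_values(x)
  ids <- intersect(ids, rownames(v))
  oca <- predict(clock, v[ids, , drop = FALSE])
  age <- align_age(chron_age, ids)
  ocaa <- compute_ocaa(oca, age)
  ocaa_std <- if (sum(!is.na(ocaa)) > 1 && sd(ocaa, na.rm = TRUE) > 0)
    as.numeric(scale(ocaa)) else rep(NA_real_, length(ocaa))
  data.frame(
    individual_id = ids, clock_name = clock_name,
    oca = unname(oca), ocaa = unname(ocaa), ocaa_std = ocaa_std,
    stringsAsFactors = FALSE
  )
}
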