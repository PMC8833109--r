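## ---------------------------------------------------------------------------
## Clock variants beyond the per-assay standard clock: stability-selected
## "core" clocks, the mega-omics merge, and principal-component clocks.
## ---------------------------------------------------------------------------

#' Stability selection of core clock features
#'
#' Repeats the full clock-construction procedure (fresh 75/25 split, k-fold
#' cross-validated elastic net) a number of times, records how often each
#' feature is selected, and retrains a "core" clock on the features whose
#' selection frequency exceeds the threshold.  Per-iteration seeds are
#' derived from the master seed and the iteration index, so results do not
#' depend on execution order.
#'
#' @param x an \code{\link{omics_matrix}} or matrix.
#' @param chron_age named age vector.
#' @param iterations number of repeats (default 500).
#' @param threshold selection-frequency threshold for the core set
#'   (default 0.95, i.e. features selected in more than 95\% of repeats).
#' @param alpha,nfolds passed to \code{\link{omics_clock}}.
#' @param seed master seed.
#' @return list of class \code{stability_result}: \code{frequency} (named,
#'   all features), \code{iterations}, \code{threshold},
#'   \code{core_features}, and \code{core_clock} (an \code{omics_clock}
#'   refitted with the full procedure on the core features).
#' @export
stability_select <- function(x, chron_age, iterations = 500, threshold = 0.95,
                             alpha = 0.5, nfolds = 10, seed = 1L) {
  v <- clock_values(x)
  counts <- setNames(numeric(ncol(v)), colnames(v))
  test_r <- numeric(iterations)
  for (i in seq_len(iterations)) {
    it_seed <- derive_seed(seed, "stability", i)
    fit <- omics_clock(v, chron_age, alpha = alpha, nfolds = nfolds,
                       seed = it_seed,
                       assay_name = if (inherits(x, "omics_matrix"))
                         x$assay_name else "assay")
    counts[names(fit$coefficients)] <- counts[names(fit$coefficients)] + 1
    test_r[i] <- fit$test_r
  }
  freq <- counts / iterations
  core <- names(freq)[freq > threshold]
  if (length(core) == 0)
    stopf("no feature selected in more than %.0f%% of %d iterations; consider a lower threshold",
          100 * threshold, iterations)
  core_clock <- omics_clock(v[, core, drop = FALSE], chron_age,
                            alpha = alpha, nfolds = nfolds,
                            seed = derive_seed(seed, "core"),
                            assay_name = if (inherits(x, "omics_matrix"))
                              paste0(x$assay_name, "_core") else "core")
  structure(
    list(frequency = freq, iterations = iterations, threshold = threshold,
         core_features = core, core_clock = core_clock,
         iteration_test_r = test_r),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result: %d iterations, %d/%d features above %.0f%% selection>\n",
    x$iterations, length(x$core_features), length(x$frequency),
    100 * x$threshold
  ))
  invisible(x)
}

#' Merge assays into a mega-omics matrix
#'
#' Column-binds all features of all assays over the intersection of their
#' individuals, prefixing feature ids with the assay name so their origin
#' remains traceable (e.g. for reporting the assay shares of the selected
#' features of a merged clock).
#'
#' @param assays named list of \code{\link{omics_matrix}} objects (already
#'   corrected and standardised).
#' @return an \code{omics_matrix} named "mega_omics".
#' @export
build_mega_matrix <- function(assays) {
  if (length(assays) == 0) stopf("no assays to merge")
  if (length(assays) == 1) return(assays[[1]])
  ids <- Reduce(intersect, lapply(assays, individual_ids))
  if (length(ids) == 0) stopf("no individuals shared across all assays")
  blocks <- lapply(assays, function(a) {
    b <- a$values[ids, , drop = FALSE]
    colnames(b) <- paste(a$assay_name, colnames(b), sep = ".")
    b
  })
  merged <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(merged)))
    stopf("duplicate feature ids after assay prefixing")
  covars <- assays[[1]]$covariates
  if (!is.null(covars)) covars <- covars[ids, , drop = FALSE]
  omics_matrix(merged, assay_name = "mega_omics", covariates = covars)
}

#' Assay shares of a merged clock's selected features
#'
#' @param clock an \code{omics_clock} fitted on a mega-omics matrix whose
#'   feature ids carry \code{assay.feature} prefixes.
#' @return named proportions of selected features per assay.
#' @export
mega_feature_shares <- function(clock) {
  feats <- names(clock$coefficients)
  if (length(feats) == 0) return(setNames(numeric(0), character(0)))
  assay <- sub("\\..*$", "", feats)
  tab <- table(assay)
  setNames(as.numeric(tab) / length(feats), names(tab))
}

#' Fit a principal-component ageing clock
#'
#' Principal components are computed on the training rows only; test (and
#' any later) individuals are projected with the stored training rotation
#' and centres before the elastic net is fitted on component scores.
#'
#' @param x an \code{\link{omics_matrix}} or matrix (corrected, scaled).
#' @param n_components number of leading components to use (commonly 3, 5,
#'   10 or 20; must not exceed the training-data rank).
#' @param chron_age named age vector.
#' @param train_ids,test_ids optional explicit split of complete-case
#'   individuals; a fresh 75/25 split is drawn when \code{NULL}.
#' @param alpha,nfolds,seed as in \code{\link{omics_clock}}.
#' @return object of classes \code{c("pc_clock", "omics_clock")}; predict
#'   accepts the original feature space.
#' @export
pc_clock <- function(x, n_components, chron_age, train_ids = NULL,
                     test_ids = NULL, alpha = 0.5, nfolds = 10, seed = 1L) {
  v <- clock_values(x)
  complete <- rownames(v)[complete.cases(v)]
  if (is.null(train_ids)) {
    sp <- split_cohort(complete, fraction = 0.75,
                       seed = derive_seed(seed, "split"))
    train_ids <- sp$train_ids
    test_ids <- sp$test_ids
  }
  train_ids <- intersect(train_ids, complete)
  if (is.null(test_ids)) test_ids <- setdiff(complete, train_ids)

  xt <- v[train_ids, , drop = FALSE]
  pca <- prcomp(xt, center = TRUE, scale. = FALSE)
  rank <- sum(pca$sdev > 1e-10)
  if (n_components > rank)
    stopf("n_components = %d exceeds training-data rank %d", n_components, rank)

  scores <- project_pcs(v[c(train_ids, intersect(test_ids, complete)), ,
                          drop = FALSE], pca, n_components)
  name <- sprintf("%s_pc%d",
                  if (inherits(x, "omics_matrix")) x$assay_name else "assay",
                  n_components)
  fit <- omics_clock(scores, chron_age, train_ids = train_ids,
                     test_ids = intersect(test_ids, complete), alpha = alpha,
                     nfolds = min(nfolds, floor(length(train_ids) / 2)),
                     seed = seed, assay_name = name)
  fit$pca_center <- pca$center
  fit$pca_rotation <- pca$rotation[, seq_len(n_components), drop = FALSE]
  class(fit) <- c("pc_clock", class(fit))
  fit
}

project_pcs <- function(v, pca, n_components) {
  s <- sweep(v, 2, pca$center) %*% pca$rotation[, seq_len(n_components),
                                                drop = FALSE]
  colnames(s) <- colnames(pca$rotation)[seq_len(n_components)]
  s
}

#' @export
predict.pc_clock <- function(object, newdata, ...) {
  v <- clock_values(newdata)
  if (all(names(object$coefficients) %in% colnames(v)))
    return(NextMethod())  # already component scores
  absent <- setdiff(rownames(object$pca_rotation), colnames(v))
  if (length(absent))
    stopf("pc clock '%s': features absent from data: %s", object$assay_name,
          paste(head(absent, 5), collapse = ", "))
  scores <- matrix(NA_real_, nrow(v), ncol(object$pca_rotation),
                   dimnames = list(rownames(v), colnames(object$pca_rotation)))
  ok <- complete.cases(v[, rownames(object$pca_rotation), drop = FALSE])
  scores[ok, ] <- project_pcs(
    v[ok, rownames(object$pca_rotation), drop = FALSE],
    list(center = object$pca_center, rotation = object$pca_rotation),
    ncol(object$pca_rotation)
  )
  oca <- rep(NA_real_, nrow(v))
  names(oca) <- rownames(v)
  oca[ok] <- predict.omics_clock(object, scores[ok, , drop = FALSE])
  oca
}
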