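## ---------------------------------------------------------------------------
## OCAA-health associations.  Outcomes are first screened for a positive
## chronological-age association (one-sided, BH FDR < 10%, and > 5 incident
## cases for diseases); only eligible outcomes are tested against clock age
## accelerations.  Effects are rescaled into per-year-of-chronAge units by
## dividing by the chronAge effect (trait-by-trait for risk factors, a
## single pooled log hazard ratio for diseases), shrunk under a N(0, 1)
## prior, and aggregated by inverse-variance weighting.
## ---------------------------------------------------------------------------

#' One-sided chronAge screen for a risk factor
#'
#' Least-squares fit of the standardised outcome on chronological age and
#' sex; the reported p-value is the upper normal tail of the Wald z for
#' the age coefficient (H1: the outcome increases with age).
#'
#' @param outcome numeric vector (standardised internally).
#' @param chron_age,sex covariate vectors aligned with \code{outcome}.
#' @param outcome_name label.
#' @return list of class \code{screen_result} with chron_age_beta (per
#'   year, SD units), se, p_one_sided, n, n_events (NA for risk factors).
#' @export
screen_chronage_risk_factor <- function(outcome, chron_age, sex,
                                        outcome_name = "outcome") {
  ok <- !is.na(outcome) & !is.na(chron_age) & !is.na(sex)
  d <- data.frame(y = as.numeric(scale(outcome[ok])),
                  age = chron_age[ok], sex = sex[ok])
  fit <- lm(y ~ age + sex, data = d)
  sm <- summary(fit)$coefficients
  structure(
    list(outcome_name = outcome_name, outcome_type = "risk_factor",
         chron_age_beta = sm["age", 1], se = sm["age", 2],
         p_one_sided = one_sided_p(sm["age", 1], sm["age", 2]),
         n = nrow(d), n_events = NA_integer_, converged = TRUE),
    class = "screen_result"
  )
}

disease_surv_data <- function(records, chron_age, sex, ocaa = NULL,
                              smoking = NULL) {
  ## prevalent cases are excluded entirely; time axis is years since
  ## assessment, censored at the recorded censor time
  idx <- match(records$individual_id, names(chron_age))
  if (anyNA(idx)) stopf("disease records contain unknown individual ids")
  d <- data.frame(
    id = records$individual_id,
    time = ifelse(records$event_flag & !records$prevalent_flag,
                  records$event_time, records$censor_time),
    event = as.integer(records$event_flag & !records$prevalent_flag),
    age = as.numeric(chron_age[idx]),
    sex = sex[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(ocaa)) d$ocaa <- as.numeric(ocaa[match(d$id, names(ocaa))])
  if (!is.null(smoking)) d$smoking <- as.numeric(smoking[idx])
  d <- d[!records$prevalent_flag, , drop = FALSE]
  d[complete.cases(d), , drop = FALSE]
}

#' One-sided chronAge screen for an incident disease
#'
#' Cox proportional-hazards fit (Efron ties) of time from assessment to
#' first incidence, with chronological age and sex as covariates and the
#' baseline hazard on the time-since-assessment axis.  Prevalent cases
#' (event before baseline) are excluded before fitting.
#'
#' @param records data.frame of event records for one disease (columns as
#'   produced by \code{\link{simulate_disease_times}}).
#' @param chron_age,sex named vectors (by individual id).
#' @param outcome_name label (default: the disease name in the records).
#' @return list of class \code{screen_result}; \code{chron_age_beta} is a
#'   log hazard ratio per year.
#' @export
screen_chronage_disease <- function(records, chron_age, sex,
                                    outcome_name = NULL) {
  outcome_name <- outcome_name %||% records$disease_name[1]
  d <- disease_surv_data(records, chron_age, sex)
  n_events <- sum(d$event)
  if (n_events < 2) stopf("disease '%s': fewer than 2 incident events", outcome_name)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ age + sex, data = d,
                    ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  structure(
    list(outcome_name = outcome_name, outcome_type = "disease",
         chron_age_beta = sm["age", "coef"], se = sm["age", "se(coef)"],
         p_one_sided = one_sided_p(sm["age", "coef"], sm["age", "se(coef)"]),
         n = nrow(d), n_events = n_events, converged = converged),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen '%s' (%s): beta=%.4f se=%.4f p=%.3g n=%d%s>\n",
    x$outcome_name, x$outcome_type, x$chron_age_beta, x$se, x$p_one_sided,
    x$n, if (!is.na(x$n_events)) sprintf(" events=%d", x$n_events) else ""
  ))
  invisible(x)
}

#' Benjamini-Hochberg FDR pass flags
#'
#' Standard step-up procedure on the supplied p-value family.
#'
#' @param p_values numeric vector of p-values (one family).
#' @param q FDR level (default 0.10).
#' @return logical vector of pass flags.
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  if (length(p_values) == 0) return(logical(0))
  p.adjust(p_values, method = "BH") <= q
}

#' Screen all outcomes for chronAge association
#'
#' Runs the risk-factor and disease screens, applies BH FDR within each
#' outcome-type family, and marks eligibility: a positive age effect, FDR
#' pass, and (diseases) more than \code{min_cases} incident cases.
#' Ineligible outcomes are never tested against OCAA downstream.
#'
#' @param risk_factors data.frame with individual_id plus one column per
#'   risk factor.
#' @param disease data.frame of event records for all diseases.
#' @param chron_age,sex named vectors (by individual id).
#' @param q FDR level (default 0.10).
#' @param min_cases minimum incident cases for disease eligibility
#'   (default 5, i.e. eligibility requires more than 5).
#' @return data.frame, one row per outcome, with the screen statistics,
#'   \code{fdr_pass} and \code{eligible}.
#' @export
screen_outcomes <- function(risk_factors, disease, chron_age, sex,
                            q = 0.10, min_cases = 5) {
  rf_names <- setdiff(names(risk_factors), "individual_id")
  idx <- match(risk_factors$individual_id, names(chron_age))
  rf_rows <- lapply(rf_names, function(nm) {
    s <- screen_chronage_risk_factor(risk_factors[[nm]], chron_age[idx],
                                     sex[idx], outcome_name = nm)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  })
  dz_rows <- lapply(split(disease, disease$disease_name), function(rec) {
    s <- screen_chronage_disease(rec, chron_age, sex)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, rf_rows), do.call(rbind, dz_rows))
  rownames(out) <- NULL
  out$fdr_pass <- FALSE
  for (type in unique(out$outcome_type)) {
    fam <- out$outcome_type == type
    out$fdr_pass[fam] <- bh_fdr(out$p_one_sided[fam], q = q)
  }
  out$eligible <- out$chron_age_beta > 0 & out$fdr_pass &
    (out$outcome_type == "risk_factor" |
       (!is.na(out$n_events) & out$n_events > min_cases))
  out
}

#' OCAA effect on a risk factor
#'
#' Linear regression of the standardised outcome on the clock's age
#' acceleration with chronological age and sex (and optionally smoking) as
#' covariates.  The effect is rescaled into per-year-of-chronAge units by
#' dividing by the outcome's own chronAge effect from the screening step,
#' and shrunk under a N(0, 1) prior.
#'
#' @param outcome numeric vector (standardised internally).
#' @param ocaa clock age acceleration (years), aligned with outcome.
#' @param chron_age,sex covariates aligned with outcome.
#' @param chron_age_beta the outcome's chronAge effect (the rescaling
#'   divisor, from \code{\link{screen_chronage_risk_factor}}).
#' @param smoking optional binary confounder.
#' @param clock_name,outcome_name labels.
#' @return list of class \code{association_result}.
#' @export
associate_ocaa_risk_factor <- function(outcome, ocaa, chron_age, sex,
                                       chron_age_beta, smoking = NULL,
                                       clock_name = "clock",
                                       outcome_name = "outcome") {
  d <- data.frame(y = as.numeric(scale(outcome)), ocaa = ocaa,
                  age = chron_age, sex = sex)
  if (!is.null(smoking)) d$smoking <- smoking
  d <- d[complete.cases(d), , drop = FALSE]
  fit <- lm(y ~ ., data = d)
  sm <- summary(fit)$coefficients
  beta <- sm["ocaa", 1]
  se <- sm["ocaa", 2]
  structure(
    list(clock_name = clock_name, outcome_name = outcome_name,
         outcome_type = "risk_factor", beta = beta, se = se,
         p_one_sided = one_sided_p(beta, se),
         rescaled_beta = if (chron_age_beta != 0) beta / chron_age_beta
                         else NA_real_,
         shrunk_beta = shrink_beta(beta, se),
         n_used = nrow(d), n_events = NA_integer_, converged = TRUE),
    class = "association_result"
  )
}

#' OCAA effect on an incident disease
#'
#' Cox proportional-hazards fit with the clock's age acceleration,
#' chronological age and sex as covariates, prevalent cases excluded.
#' The OCAA log hazard ratio is rescaled by the magnitude of the pooled
#' per-year chronAge effect (default 0.0492 log HR per year, a doubling of
#' risk every 14 years), giving the effect of one year of OCAA in years of
#' chronAge.
#'
#' @param records event records for one disease.
#' @param ocaa named OCAA vector (years, by individual id).
#' @param chron_age,sex named covariate vectors.
#' @param pooled_divisor magnitude of the pooled chronAge log hazard ratio
#'   per year used as the rescaling divisor (default 0.0492).
#' @param smoking optional named binary confounder.
#' @param clock_name,outcome_name labels.
#' @return list of class \code{association_result}; \code{beta} is the
#'   OCAA log hazard ratio per year.
#' @export
associate_ocaa_disease <- function(records, ocaa, chron_age, sex,
                                   pooled_divisor = 0.0492, smoking = NULL,
                                   clock_name = "clock",
                                   outcome_name = NULL) {
  outcome_name <- outcome_name %||% records$disease_name[1]
  d <- disease_surv_data(records, chron_age, sex, ocaa = ocaa,
                         smoking = smoking)
  n_events <- sum(d$event)
  if (n_events < 2) stopf("disease '%s': fewer than 2 incident events", outcome_name)
  converged <- TRUE
  rhs <- if (is.null(smoking)) ~ ocaa + age + sex else ~ ocaa + age + sex + smoking
  fit <- withCallingHandlers(
    survival::coxph(as.formula(paste("survival::Surv(time, event)",
                                     paste(deparse(rhs), collapse = ""))),
                    data = d, ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  beta <- sm["ocaa", "coef"]
  se <- sm["ocaa", "se(coef)"]
  structure(
    list(clock_name = clock_name, outcome_name = outcome_name,
         outcome_type = "disease", beta = beta, se = se,
         p_one_sided = one_sided_p(beta, se),
         rescaled_beta = beta / abs(pooled_divisor),
         shrunk_beta = shrink_beta(beta, se),
         n_used = nrow(d), n_events = n_events, converged = converged),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association %s ~ %s (%s): beta=%.4f se=%.4f p=%.3g rescaled=%.3f>\n",
    x$outcome_name, x$clock_name, x$outcome_type, x$beta, x$se,
    x$p_one_sided, x$rescaled_beta
  ))
  invisible(x)
}

#' Posterior-mean shrinkage of an effect estimate
#'
#' Normal-normal conjugate update with a N(0, 1) prior on the effect:
#' the posterior mean is \code{beta / (1 + se^2)}, so estimates with large
#' standard errors are pulled harder towards zero.
#'
#' @param beta observed effect.
#' @param se its standard error.
#' @return shrunk effect.
#' @export
shrink_beta <- function(beta, se) beta / (1 + se^2)

#' Inverse-variance-weighted mean effect
#'
#' Aggregates effects over outcomes (or clocks).  Because outcomes and
#' predictors are correlated, the independence assumption behind the
#' pooled SE is violated; the SE is therefore indicative only (a sense of
#' magnitude, not a formal test).
#'
#' @param betas,ses numeric vectors of effects and standard errors.
#' @return list with \code{pooled_beta} and \code{indicative_se}.
#' @export
ivw_mean <- function(betas, ses) {
  ok <- !is.na(betas) & !is.na(ses) & ses > 0
  if (!any(ok)) return(list(pooled_beta = NA_real_, indicative_se = NA_real_))
  w <- 1 / ses[ok]^2
  list(pooled_beta = sum(betas[ok] * w) / sum(w),
       indicative_se = sqrt(1 / sum(w)))
}

#' Two-sided test for a sex difference in effect size
#'
#' Normal z-test on the difference of two independent estimates:
#' \code{z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)}.
#'
#' @param beta_m,se_m effect and SE in males.
#' @param beta_f,se_f effect and SE in females.
#' @return two-sided p-value.
#' @export
sex_difference_test <- function(beta_m, se_m, beta_f, se_f) {
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Enrichment of positive and nominally significant OCAA effects
#'
#' @param results data.frame of association results (columns
#'   \code{outcome_type}, \code{beta}, \code{p_one_sided}).
#' @param alpha nominal one-sided level (default 0.05).
#' @return data.frame per outcome type: number of tests, proportion of
#'   positive effects, proportion nominally significant.
#' @export
enrichment_summary <- function(results, alpha = 0.05) {
  types <- unique(results$outcome_type)
  do.call(rbind, lapply(types, function(ty) {
    r <- results[results$outcome_type == ty, , drop = FALSE]
    data.frame(
      outcome_type = ty, n_tests = nrow(r),
      prop_positive = mean(r$beta > 0),
      prop_nominal = mean(r$p_one_sided < alpha),
      stringsAsFactors = FALSE
    )
  }))
}

#' Risk-doubling horizon implied by a per-year log hazard ratio
#'
#' A log hazard ratio b per year of age doubles risk every
#' \code{log(2) / b} years; for b = 0.0492 that is about every 14 years.
#'
#' @param log_hr_per_year per-year log hazard ratio (> 0).
#' @return years to doubling of risk.
#' @export
hazard_doubling_time <- function(log_hr_per_year) {
  if (any(log_hr_per_year <= 0)) stopf("log hazard ratio must be positive")
  log(2) / log_hr_per_year
}

#' Default clock-outcome exclusion list
#'
#' Clock-outcome pairs never tested because the clock's own features are
#' (close to) the outcome: assays carrying metabolite or lipid features
#' are not tested against creatinine or total cholesterol.  Editable:
#' supply your own data.frame(clock_name, outcome_name) to
#' \code{\link{associate_all}}.
#'
#' @return data.frame with columns clock_name and outcome_name.
#' @export
default_exclusions <- function() {
  data.frame(
    clock_name = c("metabolite_panel", "metabolite_panel", "lipidomics"),
    outcome_name = c("creatinine", "total_cholesterol", "total_cholesterol"),
    stringsAsFactors = FALSE
  )
}

#' Run all eligible OCAA-outcome associations
#'
#' For every clock and every screening-eligible outcome (minus excluded
#' pairs) fits the appropriate model, rescales, shrinks, and flags BH FDR
#' within each (outcome type) family.
#'
#' @param ocaa_table data.frame with columns individual_id, clock_name,
#'   ocaa (long format, as from \code{\link{clock_age_table}}).
#' @param screen result of \code{\link{screen_outcomes}}.
#' @param risk_factors,disease,chron_age,sex as in
#'   \code{\link{screen_outcomes}}.
#' @param pooled_divisor pooled disease rescaling divisor (default 0.0492).
#' @param exclusions data.frame(clock_name, outcome_name) of forbidden
#'   pairs (default \code{\link{default_exclusions}}).
#' @param smoking optional named binary vector, fitted as an extra
#'   covariate when supplied.
#' @param q FDR level (default 0.10).
#' @return data.frame, one row per clock-outcome test.
#' @export
associate_all <- function(ocaa_table, screen, risk_factors, disease,
                          chron_age, sex, pooled_divisor = 0.0492,
                          exclusions = default_exclusions(), smoking = NULL,
                          q = 0.10) {
  eligible <- screen[screen$eligible, , drop = FALSE]
  clocks <- unique(ocaa_table$clock_name)
  rows <- list()
  for (cl in clocks) {
    tab <- ocaa_table[ocaa_table$clock_name == cl, , drop = FALSE]
    ocaa <- setNames(tab$ocaa, tab$individual_id)
    for (i in seq_len(nrow(eligible))) {
      out_nm <- eligible$outcome_name[i]
      if (any(exclusions$clock_name == cl & exclusions$outcome_name == out_nm))
        next
      res <- if (eligible$outcome_type[i] == "risk_factor") {
        idx <- match(risk_factors$individual_id, names(ocaa))
        associate_ocaa_risk_factor(
          risk_factors[[out_nm]], ocaa[idx],
          chron_age[risk_factors$individual_id],
          sex[risk_factors$individual_id],
          chron_age_beta = eligible$chron_age_beta[i],
          smoking = if (is.null(smoking)) NULL
                    else smoking[risk_factors$individual_id],
          clock_name = cl, outcome_name = out_nm
        )
      } else {
        rec <- disease[disease$disease_name == out_nm, , drop = FALSE]
        associate_ocaa_disease(
          rec, ocaa, chron_age, sex, pooled_divisor = pooled_divisor,
          smoking = smoking, clock_name = cl, outcome_name = out_nm
        )
      }
      rows[[length(rows) + 1]] <-
        as.data.frame(unclass(res), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  out$fdr_pass <- FALSE
  for (ty in unique(out$outcome_type)) {
    fam <- out$outcome_type == ty & out$converged
    out$fdr_pass[fam] <- bh_fdr(out$p_one_sided[fam], q = q)
  }
  out
}

#' Sex-consistency of OCAA-disease associations
#'
#' Mirrors the pooled-then-stratified procedure: restrict to OCAA-disease
#' associations nominally significant (one-sided p < 0.05) in the pooled
#' analysis, re-screen each disease within each sex with the same
#' eligibility rule (positive chronAge effect, BH FDR, > min_cases), and
#' for associations assessable in both sexes count how often the effect
#' sign agrees.  Discrepant pairs get a two-sided z-test for a difference
#' in effect size.
#'
#' @inheritParams associate_all
#' @param pooled pooled association results (from
#'   \code{\link{associate_all}}), disease rows only are used.
#' @param min_cases disease eligibility threshold per sex (default 5).
#' @return list with \code{n_assessed}, \code{prop_consistent}, and a
#'   data.frame \code{detail} of per-association sex-specific effects.
#' @export
sex_sign_consistency <- function(pooled, ocaa_table, disease, chron_age, sex,
                                 q = 0.10, min_cases = 5) {
  hits <- pooled[pooled$outcome_type == "disease" &
                   pooled$p_one_sided < 0.05, , drop = FALSE]
  if (nrow(hits) == 0)
    return(list(n_assessed = 0L, prop_consistent = NA_real_,
                detail = NULL))
  sexes <- levels(factor(sex))
  ## per-sex screening of each disease appearing among the hits
  per_sex_ok <- list()
  per_sex_screen <- list()
  for (sx in sexes) {
    ids <- names(sex)[sex == sx]
    rows <- lapply(split(disease, disease$disease_name), function(rec) {
      rec <- rec[rec$individual_id %in% ids, , drop = FALSE]
      ## sex is constant within a stratum, so the screen model is age only
      s <- tryCatch({
        d <- disease_surv_data(rec, chron_age, sex)
        if (sum(d$event) < 2) return(NULL)
        fit <- survival::coxph(survival::Surv(time, event) ~ age, data = d,
                               ties = "efron")
        sm <- summary(fit)$coefficients
        list(outcome_name = rec$disease_name[1], outcome_type = "disease",
             chron_age_beta = sm["age", "coef"], se = sm["age", "se(coef)"],
             p_one_sided = one_sided_p(sm["age", "coef"],
                                       sm["age", "se(coef)"]),
             n = nrow(d), n_events = sum(d$event), converged = TRUE)
      }, error = function(e) NULL)
      if (is.null(s)) return(NULL)
      as.data.frame(s, stringsAsFactors = FALSE)
    })
    scr <- do.call(rbind, Filter(Negate(is.null), rows))
    if (!is.null(scr) && nrow(scr)) {
      scr$fdr_pass <- bh_fdr(scr$p_one_sided, q = q)
      scr$eligible <- scr$chron_age_beta > 0 & scr$fdr_pass &
        scr$n_events > min_cases
    }
    per_sex_screen[[sx]] <- scr
    per_sex_ok[[sx]] <- if (is.null(scr)) character()
                        else scr$outcome_name[scr$eligible]
  }
  assessable <- Reduce(intersect, per_sex_ok)

  detail <- list()
  for (i in seq_len(nrow(hits))) {
    out_nm <- hits$outcome_name[i]
    if (!(out_nm %in% assessable)) next
    cl <- hits$clock_name[i]
    tab <- ocaa_table[ocaa_table$clock_name == cl, , drop = FALSE]
    ocaa <- setNames(tab$ocaa, tab$individual_id)
    est <- lapply(sexes, function(sx) {
      ids <- names(sex)[sex == sx]
      rec <- disease[disease$disease_name == out_nm &
                       disease$individual_id %in% ids, , drop = FALSE]
      tryCatch({
        d <- disease_surv_data(rec, chron_age, sex, ocaa = ocaa)
        if (sum(d$event) < 2) return(NULL)
        fit <- survival::coxph(survival::Surv(time, event) ~ ocaa + age,
                               data = d, ties = "efron")
        sm <- summary(fit)$coefficients
        ## standardised effect: per SD of OCAA within this sex stratum
        list(beta = sm["ocaa", "coef"] * sd(d$ocaa),
             se = sm["ocaa", "se(coef)"] * sd(d$ocaa))
      }, error = function(e) NULL)
    })
    if (any(vapply(est, is.null, logical(1)))) next
    b <- vapply(est, `[[`, numeric(1), "beta")
    s <- vapply(est, `[[`, numeric(1), "se")
    detail[[length(detail) + 1]] <- data.frame(
      clock_name = cl, outcome_name = out_nm,
      beta_f = b[1], se_f = s[1], beta_m = b[2], se_m = s[2],
      consistent = sign(b[1]) == sign(b[2]),
      p_difference = sex_difference_test(b[2], s[2], b[1], s[1]),
      stringsAsFactors = FALSE
    )
  }
  detail <- do.call(rbind, detail)
  list(
    n_assessed = if (is.null(detail)) 0L else nrow(detail),
    prop_consistent = if (is.null(detail)) NA_real_
                      else mean(detail$consistent),
    detail = detail
  )
}
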