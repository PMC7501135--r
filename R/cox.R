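# Stratified Cox fits on the age time scale with delayed entry, subtype
# outcomes, Prentice case-cohort reweighting, PH diagnostics and
# between-subtype heterogeneity tests. Partial-likelihood maximisation is
# delegated to survival::coxph; this file defines the screening surface
# around it.

#' Specification of the screening Cox model
#'
#' @param strata character vector of stratification columns (baseline hazard
#'   varies freely across their combinations); default age band x centre.
#' @param covariates character vector of confounder columns entering the
#'   linear predictor alongside the exposure.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param weights optional name of a case-weight column.
#' @param robust_variance logical; use the sandwich (robust) standard error
#'   for inference. Required for Prentice-weighted case-cohort fits.
#' @param ci_level confidence level for Wald intervals (default 0.95).
#' @param time_scale `"age"`: entry/exit are ages and risk sets respect
#'   delayed entry (left truncation). `"followup"` uses time since entry.
#' @return an object of class `cox_spec`.
#' @export
#' @examples
#' cox_spec(covariates = c("energy_kcal", "smoking"))
cox_spec <- function(strata = c("age_band", "center"),
                     covariates = c("energy_kcal", "smoking", "bmi_cat",
                                    "activity", "diabetes", "education"),
                     tie_method = c("efron", "breslow"),
                     weights = NULL,
                     robust_variance = FALSE,
                     ci_level = 0.95,
                     time_scale = c("age", "followup")) {
  tie_method <- match.arg(tie_method)
  time_scale <- match.arg(time_scale)
  if (length(intersect(strata, covariates)))
    stop("strata and covariates must be disjoint")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(list(strata = strata, covariates = covariates,
                 tie_method = tie_method, weights = weights,
                 robust_variance = isTRUE(robust_variance),
                 ci_level = ci_level, time_scale = time_scale),
            class = "cox_spec")
}

cox_formula <- function(exposure, spec) {
  rhs <- c(sprintf("`%s`", exposure),
           sprintf("`%s`", spec$covariates),
           if (length(spec$strata))
             sprintf("strata(%s)",
                     paste(sprintf("`%s`", spec$strata), collapse = ", ")))
  resp <- if (spec$time_scale == "age")
    "survival::Surv(age_entry, age_exit, event)"
  else
    "survival::Surv(age_exit - age_entry, event)"
  as.formula(paste(resp, "~", paste(rhs, collapse = " + ")))
}

#' Fit the screening Cox model for one exposure
#'
#' Maximises the stratified Cox partial likelihood with the age time scale
#' and delayed entry: at age `t`, the risk set in each stratum is the set of
#' participants with `age_entry < t <= age_exit`. Strata without events
#' contribute no terms to the partial likelihood and are dropped (with a
#' message). Non-convergence and separation are reported through the
#' `converged` flag, not as errors, so that a screen over many exposures
#' never aborts.
#'
#' @param data cohort data.frame with `age_entry`, `age_exit`, `event`, the
#'   exposure, covariate and strata columns (and the weight column if the
#'   spec names one).
#' @param exposure name of the (already coded) exposure column.
#' @param spec a [cox_spec()].
#' @return an object of class `cox_fit`: `exposure_name`, `log_hr`, `se`
#'   (model-based), `robust_se` (if requested), `hr`, `ci_low`, `ci_high`
#'   (Wald, on the hazard-ratio scale, using the robust SE when the spec
#'   requests it), `p_value` (two-sided Wald), `n`, `n_events`, `converged`,
#'   and the underlying `coxph` fit in `$fit`.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(2000, n_foods = 2, n_nutrients = 0,
#'                                   seed = 5))
#' co$food_01 <- zscore(co$food_01)
#' fit_cox(co, "food_01", cox_spec(covariates = "energy_kcal"))
fit_cox <- function(data, exposure, spec = cox_spec()) {
  stopifnot(inherits(spec, "cox_spec"))
  if (!exposure %in% names(data)) stop("exposure column not found: ", exposure)
  used <- stats::complete.cases(
    data[, c("age_entry", "age_exit", "event", exposure, spec$covariates,
             spec$strata), drop = FALSE])
  if (var(data[[exposure]][used]) == 0)
    stop("exposure has zero variance on the analysis set: ", exposure)

  if (length(spec$strata)) {
    grp <- interaction(data[used, spec$strata, drop = FALSE], drop = TRUE)
    ev_by <- tapply(data$event[used], grp, sum)
    n_empty <- sum(ev_by == 0)
    if (n_empty > 0)
      message(n_empty, " event-free strat",
              if (n_empty == 1) "um contributes" else "a contribute",
              " nothing to the partial likelihood")
  }

  fml <- cox_formula(exposure, spec)
  env <- new.env(parent = environment(fml))
  env$.case_weights <- if (is.null(spec$weights)) NULL else data[[spec$weights]]
  # robust (sandwich) variance treats each participant as a cluster
  env$.cluster_id <- if (spec$robust_variance) {
    if (is.null(data$participant_id)) seq_len(nrow(data)) else
      data$participant_id
  } else NULL
  env$data <- data  # lets cox.zph and other post-hoc tools rebuild the frame
  environment(fml) <- env
  converged <- 1L
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data,
                    weights = .case_weights, cluster = .cluster_id,
                    ties = spec$tie_method,
                    robust = spec$robust_variance, model = FALSE,
                    x = TRUE, y = TRUE),
    warning = function(wrn) {
      if (grepl("did not converge|infinite|converged before|out of iterations|singular",
                conditionMessage(wrn)))
        converged <<- 0L
      invokeRestart("muffleWarning")
    })

  beta <- unname(coef(fit)[1])
  if (is.na(beta)) converged <- 0L
  model_se <- sqrt(diag(if (is.null(fit$naive.var)) fit$var else fit$naive.var))[1]
  robust_se <- if (spec$robust_variance) sqrt(diag(fit$var))[1] else NA_real_
  se_used <- if (spec$robust_variance) robust_se else model_se
  z <- qnorm(1 - (1 - spec$ci_level) / 2)

  structure(list(
    exposure_name = exposure,
    log_hr = beta, se = unname(model_se), robust_se = unname(robust_se),
    se_used = unname(se_used),
    hr = exp(beta),
    ci_low = exp(beta - z * se_used), ci_high = exp(beta + z * se_used),
    p_value = 2 * pnorm(-abs(beta / se_used)),
    n = as.integer(fit$n), n_events = as.integer(fit$nevent),
    converged = converged, spec = spec, fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit for %s: HR %.4f (%.0f%% CI %.4f-%.4f), p = %.3g\n",
              x$exposure_name, x$hr, 100 * x$spec$ci_level,
              x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  log-HR %.5f, SE %.5f%s; %d events / %d subjects%s\n",
              x$log_hr, x$se_used,
              if (x$spec$robust_variance) " (robust)" else "",
              x$n_events, x$n,
              if (x$converged) "" else "  [DID NOT CONVERGE]"))
  invisible(x)
}

#' Prepare a case-cohort file for a Prentice-weighted Cox fit
#'
#' Under Prentice weighting, subcohort members are at risk over their full
#' follow-up with weight 1, while cases outside the subcohort enter the risk
#' set only just before their own event: their entry time is set to
#' `age_exit - eps`. The returned data must be fitted with
#' `robust_variance = TRUE` (model-based variances are invalid under
#' case-cohort sampling); [fit_cox()] is used downstream unchanged.
#'
#' @param data case-cohort data.frame with an `in_subcohort` 0/1 column; all
#'   non-subcohort rows must be cases.
#' @param eps entry offset in years; default `1e-5 * (max(age_exit) -
#'   min(age_entry))` — a few hours on the age scale, far below any
#'   realistic between-subject gap yet above the tie-rounding tolerance
#'   `coxph` applies to survival times.
#' @return the data.frame with adjusted `age_entry` and a `prentice_weight`
#'   column (all 1); `attr(, "prentice_eps")` records the offset used.
#' @export
build_prentice_weights <- function(data, eps = NULL) {
  if (is.null(data$in_subcohort)) stop("in_subcohort column is required")
  bad <- data$in_subcohort == 0 & data$event == 0
  if (any(bad))
    stop("inconsistent case-cohort file: ", sum(bad),
         " non-subcohort row(s) without an event")
  if (is.null(eps))
    eps <- 1e-5 * (max(data$age_exit) - min(data$age_entry))
  outside <- data$in_subcohort == 0 & data$event == 1
  data$age_entry[outside] <- data$age_exit[outside] - eps
  data$prentice_weight <- 1
  attr(data, "prentice_eps") <- eps
  data
}

#' Test proportional hazards via the slope of the Schoenfeld residuals
#'
#' Computes scaled Schoenfeld residuals at event ages for the exposure term
#' and tests a zero slope against analysis time (identity transform, so the
#' slope is against age itself on the age scale), i.e. the usual `cox.zph`
#' score test restricted to the exposure.
#'
#' @param fit a converged [fit_cox()] result with at least 2 events.
#' @return object of class `ph_test`: `exposure_name`, `slope_stat` (the
#'   least-squares slope of the scaled residuals on time), `chisq`, and
#'   `p_value`.
#' @export
schoenfeld_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2) stop("at least 2 events are required")
  if (!fit$converged) stop("fit did not converge")
  zph <- survival::cox.zph(fit$fit, transform = "identity", terms = FALSE)
  slope <- unname(coef(lm(zph$y[, 1] ~ zph$x))[2])
  structure(list(exposure_name = fit$exposure_name,
                 slope_stat = slope,
                 chisq = unname(zph$table[1, "chisq"]),
                 p_value = unname(zph$table[1, "p"])),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat(sprintf("Schoenfeld slope test for %s: slope %.4g, chisq %.3f, p = %.3g\n",
              x$exposure_name, x$slope_stat, x$chisq, x$p_value))
  invisible(x)
}

SUBTYPE_OUTCOMES <- c("total", "localized", "advanced", "low_grade",
                      "high_grade", "aggressive", "fatal")

subtype_event <- function(data, subtype_outcome) {
  ev <- data$event == 1
  switch(subtype_outcome,
         total      = as.integer(ev),
         localized  = as.integer(ev & !is.na(data$stage) & data$stage == "localized"),
         advanced   = as.integer(ev & !is.na(data$stage) & data$stage == "advanced"),
         low_grade  = as.integer(ev & !is.na(data$grade) & data$grade == "low"),
         high_grade = as.integer(ev & !is.na(data$grade) & data$grade == "high"),
         aggressive = as.integer(ev & !is.na(data$aggressive) & data$aggressive == 1),
         fatal      = as.integer(ev & !is.na(data$fatal) & data$fatal == 1),
         stop("unknown subtype outcome: ", subtype_outcome))
}

#' Fit the screening model for a disease-subtype outcome
#'
#' Cause-specific analysis: events of the target subtype are the outcome;
#' events of other subtypes are censored at their diagnosis age (their
#' recorded exit). For `fatal`, death from the disease is the event and any
#' other exit censors.
#'
#' @param data cohort data.frame with subtype label columns (`stage`,
#'   `grade`, `aggressive`, `fatal`).
#' @param exposure name of the coded exposure column.
#' @param subtype_outcome one of `"total"`, `"localized"`, `"advanced"`,
#'   `"low_grade"`, `"high_grade"`, `"aggressive"`, `"fatal"`.
#' @param spec a [cox_spec()].
#' @return a `cox_fit`; see [fit_cox()].
#' @export
fit_subtype <- function(data, exposure, subtype_outcome, spec = cox_spec()) {
  subtype_outcome <- match.arg(subtype_outcome, SUBTYPE_OUTCOMES)
  ev <- subtype_event(data, subtype_outcome)
  if (sum(ev) == 0) stop("no events of subtype: ", subtype_outcome)
  data$event <- ev
  fit <- fit_cox(data, exposure, spec)
  fit$subtype_outcome <- subtype_outcome
  fit
}

#' Wald test of heterogeneity between two subtype-specific estimates
#'
#' Contrasts the log hazard ratios of two fits on mutually exclusive
#' outcomes: `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, treating the estimates
#' as independent, with a two-sided normal p-value. Because the two fits
#' share person-time, the independence assumption is approximate and the
#' test is anti-conservative; see the package vignette.
#'
#' @param fit1,fit2 `cox_fit` objects for mutually exclusive subtype
#'   outcomes (e.g. localized vs advanced).
#' @param subtype_axis label for the contrasted axis (e.g. `"stage"`).
#' @return object of class `het_test` with the per-subtype estimates, the
#'   z `statistic` and `p_value`.
#' @export
wald_heterogeneity <- function(fit1, fit2, subtype_axis = "stage") {
  stopifnot(inherits(fit1, "cox_fit"), inherits(fit2, "cox_fit"))
  if (is.na(fit1$se_used) || is.na(fit2$se_used))
    stop("both fits must carry standard errors")
  z <- (fit1$log_hr - fit2$log_hr) / sqrt(fit1$se_used^2 + fit2$se_used^2)
  structure(list(
    subtype_axis = subtype_axis,
    estimates = data.frame(
      subtype = c(fit1$subtype_outcome %||% "fit1",
                  fit2$subtype_outcome %||% "fit2"),
      log_hr = c(fit1$log_hr, fit2$log_hr),
      se = c(fit1$se_used, fit2$se_used)),
    statistic = z,
    p_value = 2 * pnorm(-abs(z))),
    class = "het_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.het_test <- function(x, ...) {
  cat(sprintf("Heterogeneity by %s: z = %.4f, p = %.4g\n",
              x$subtype_axis, x$statistic, x$p_value))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
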