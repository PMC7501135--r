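#' Specification of a synthetic cohort
#'
#' Collects every parameter of the synthetic-data generator in one validated
#' object. The defaults emulate the structure of a large multi-centre
#' European cohort of middle-aged men followed for prostate cancer: 92
#' dietary exposures (63 foods, 29 nutrients) with block correlation and
#' FFQ-like right-skewed marginals, total energy intake confounded with the
#' exposures, six categorical confounders, recruitment-centre and age-band
#' stratification, and a Weibull baseline hazard on the age scale calibrated
#' to roughly 5\% cumulative incidence over a 14-year administrative
#' follow-up horizon.
#'
#' @section Exposures:
#' Intakes are generated on a latent Gaussian scale with exchangeable
#' within-block correlation `exposure_correlation` (blocks of `block_size`
#' consecutive exposures emulate correlated food groups / nutrient families)
#' and then exponentiated, giving log-normal marginals: non-negative, right
#' skewed, with coefficient of variation `latent_sd` (natural log-scale SD).
#' Total energy is a positive linear combination of all intakes plus
#' Gaussian noise, so energy confounding is present by construction.
#'
#' @section Hazard model:
#' Event ages follow a Weibull proportional-hazards model with shape
#' `baseline_shape` and scale `baseline_scale` (years), left-truncated at the
#' entry age, with linear predictor
#' `sum(planted_effects * standardized exposure) + confounder effects +
#' energy effect + centre offset`, centred so that the planted baseline
#' calibration is preserved. Administrative censoring occurs at
#' `entry + admin_censor_years`.
#'
#' @param n_participants number of participants.
#' @param n_foods number of food exposures (columns `food_01`, ...).
#' @param n_nutrients number of nutrient exposures (columns `nutrient_01`, ...).
#' @param exposure_correlation within-block latent correlation, in `[0, 1)`.
#' @param block_size exposures per correlated block.
#' @param latent_sd log-scale SD of intakes (~ coefficient of variation).
#' @param energy_noise_sd SD (kcal) of the noise added to the energy column.
#' @param planted_effects named numeric vector of log hazard ratios per 1 SD
#'   of the named exposures; default none (global null).
#' @param baseline_shape,baseline_scale Weibull shape and scale (years) of the
#'   age-at-event baseline hazard.
#' @param admin_censor_years administrative follow-up horizon in years
#'   (14 for a discovery-style cohort, ~20 for a longer-running
#'   replication cohort).
#' @param entry_age_min,entry_age_max entry ages are uniform on this range,
#'   populating every age band.
#' @param age_band_width width (years) of the age-at-recruitment strata.
#' @param n_centers number of recruitment centres.
#' @param center_log_hr per-centre baseline log-hazard offsets (length
#'   `n_centers`); centres therefore have genuinely different baselines and
#'   stratification matters.
#' @param confounder_probs named list of category probability vectors for
#'   `smoking`, `bmi_cat`, `activity`, `diabetes`, `education`,
#'   `family_history`.
#' @param confounder_effects named list of per-category log hazard ratios,
#'   same shapes as `confounder_probs`.
#' @param energy_log_hr log hazard ratio per kcal of total energy.
#' @param subtype_probs list with elements `stage` (probabilities of
#'   localized / advanced / unknown), `grade` (low / high / unknown),
#'   `psa_over_20` (yes / no / unknown) and `fatal` (scalar), all conditional
#'   on an event.
#' @param missingness scalar probability that each categorical confounder is
#'   missing, independently per confounder and participant. The default 0
#'   emulates a complete-case analysis set; set it positive to emulate a
#'   pre-exclusion roster.
#' @param seed master RNG seed; all generator stages draw from seeds derived
#'   with [split_seed()].
#'
#' @return an object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()], [generate_exposures()], [generate_outcomes()]
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 500, seed = 7)
#' spec$m  # total exposures
cohort_spec <- function(n_participants,
                        n_foods = 63,
                        n_nutrients = 29,
                        exposure_correlation = 0.4,
                        block_size = 4,
                        latent_sd = 0.25,
                        energy_noise_sd = 400,
                        planted_effects = NULL,
                        baseline_shape = 6,
                        baseline_scale = 113.5,
                        admin_censor_years = 14,
                        entry_age_min = 45,
                        entry_age_max = 70,
                        age_band_width = 5,
                        n_centers = 8,
                        center_log_hr = NULL,
                        confounder_probs = NULL,
                        confounder_effects = NULL,
                        energy_log_hr = 5e-5,
                        subtype_probs = NULL,
                        missingness = 0,
                        seed = 1L) {
  default_probs <- list(
    smoking        = c(never = 0.35, former = 0.34, current = 0.31),
    bmi_cat        = c(b1 = 0.03, b2 = 0.12, b3 = 0.20, b4 = 0.45, b5 = 0.15, b6 = 0.05),
    activity       = c(inactive = 0.15, mod_inactive = 0.34, mod_active = 0.31, active = 0.20),
    diabetes       = c(no = 0.96, yes = 0.04),
    education      = c(primary = 0.25, technical = 0.25, secondary = 0.22, longer = 0.28),
    family_history = c(no = 0.90, yes = 0.10))
  default_effects <- list(
    smoking        = c(0, 0.10, 0.20),
    bmi_cat        = c(0, 0, 0, 0.05, 0.10, 0.15),
    activity       = c(0, -0.03, -0.06, -0.10),
    diabetes       = c(0, -0.10),
    education      = c(0, 0.02, 0.04, 0.05),
    family_history = c(0, 0.30))
  default_subtypes <- list(
    stage       = c(localized = 0.392, advanced = 0.193, unknown = 0.415),
    grade       = c(low = 0.535, high = 0.098, unknown = 0.367),
    psa_over_20 = c(yes = 0.08, no = 0.62, unknown = 0.30),
    fatal       = 0.12)

  confounder_probs <- if (is.null(confounder_probs)) default_probs else
    modifyList(default_probs, confounder_probs)
  confounder_effects <- if (is.null(confounder_effects)) default_effects else
    modifyList(default_effects, confounder_effects)
  subtype_probs <- if (is.null(subtype_probs)) default_subtypes else
    modifyList(default_subtypes, subtype_probs)
  if (is.null(center_log_hr))
    center_log_hr <- if (n_centers == 1) 0 else
      seq(-0.15, 0.15, length.out = n_centers)

  spec <- list(
    n_participants = as.integer(n_participants),
    n_foods = as.integer(n_foods), n_nutrients = as.integer(n_nutrients),
    m = as.integer(n_foods + n_nutrients),
    exposure_correlation = exposure_correlation,
    block_size = as.integer(block_size),
    latent_sd = latent_sd, energy_noise_sd = energy_noise_sd,
    planted_effects = planted_effects,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    admin_censor_years = admin_censor_years,
    entry_age_min = entry_age_min, entry_age_max = entry_age_max,
    age_band_width = age_band_width,
    n_centers = as.integer(n_centers), center_log_hr = center_log_hr,
    confounder_probs = confounder_probs,
    confounder_effects = confounder_effects,
    energy_log_hr = energy_log_hr,
    subtype_probs = subtype_probs,
    missingness = missingness,
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_participants < 1) stop("n_participants must be positive")
    if (n_foods < 0 || n_nutrients < 0 || m != n_foods + n_nutrients)
      stop("n_foods + n_nutrients must equal the total exposure count")
    if (exposure_correlation < 0 || exposure_correlation >= 1)
      stop("exposure_correlation must be in [0, 1)")
    if (baseline_shape <= 0 || baseline_scale <= 0)
      stop("Weibull shape and scale must be positive")
    if (admin_censor_years <= 0) stop("admin_censor_years must be positive")
    if (entry_age_max <= entry_age_min) stop("entry age range is empty")
    if (length(center_log_hr) != n_centers)
      stop("center_log_hr must have one offset per centre")
    if (missingness < 0 || missingness > 1) stop("missingness must be in [0, 1]")
    for (nm in names(confounder_probs)) {
      p <- confounder_probs[[nm]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("confounder_probs$", nm, " must be a probability vector")
      if (length(confounder_effects[[nm]]) != length(p))
        stop("confounder_effects$", nm, " length mismatch")
    }
    for (nm in c("stage", "grade", "psa_over_20")) {
      p <- subtype_probs[[nm]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("subtype_probs$", nm, " must be a probability vector")
    }
    if (subtype_probs$fatal < 0 || subtype_probs$fatal > 1)
      stop("subtype_probs$fatal must be in [0, 1]")
    if (!is.null(planted_effects) &&
        (is.null(names(planted_effects)) || any(names(planted_effects) == "")))
      stop("planted_effects must be a named vector of log hazard ratios")
  })
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  participants: %d   exposures: %d (%d foods + %d nutrients)\n",
              x$n_participants, x$m, x$n_foods, x$n_nutrients))
  cat(sprintf("  within-block correlation %.2f (blocks of %d), latent SD %.2f\n",
              x$exposure_correlation, x$block_size, x$latent_sd))
  cat(sprintf("  baseline: Weibull(shape %.3g, scale %.4g y); censoring at entry + %g y\n",
              x$baseline_shape, x$baseline_scale, x$admin_censor_years))
  cat(sprintf("  entry ages U(%g, %g), %d centres, seed %d\n",
              x$entry_age_min, x$entry_age_max, x$n_centers, x$seed))
  if (!is.null(x$planted_effects)) {
    cat("  planted log-HRs per SD:\n")
    for (nm in names(x$planted_effects))
      cat(sprintf("    %s: %.4f\n", nm, x$planted_effects[[nm]]))
  } else cat("  no planted effects (global null)\n")
  invisible(x)
}

#' Exposure column names for a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return character vector `food_01 ... nutrient_01 ...`.
#' @export
exposure_names <- function(spec) {
  c(sprintf("food_%02d", seq_len(spec$n_foods)),
    sprintf("nutrient_%02d", seq_len(spec$n_nutrients)))
}

#' Exposure kinds (food or nutrient) for a set of exposure names
#'
#' Nutrient exposures are energy-adjusted by the residual method before
#' standardization; food exposures are standardized raw, with total energy
#' kept as a model covariate.
#'
#' @param names character vector of exposure column names.
#' @return named character vector, values `"food"` or `"nutrient"`.
#' @export
exposure_kinds <- function(names) {
  setNames(ifelse(grepl("^nutrient", names), "nutrient", "food"), names)
}
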