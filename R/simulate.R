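# Synthetic cohort generation: correlated FFQ-like intakes, energy
# confounding, categorical confounders, Weibull proportional-hazards events
# on the age scale with delayed entry, subtype labels, case-cohort draws.

CONFOUNDER_NAMES <- c("smoking", "bmi_cat", "activity", "diabetes",
                      "education", "family_history")

#' Generate correlated exposure intakes and energy columns
#'
#' Intakes are drawn on a latent Gaussian scale with exchangeable
#' within-block correlation (blocks of `spec$block_size` consecutive
#' exposures) and exponentiated, giving right-skewed, strictly positive,
#' FFQ-like marginals whose rank correlation matches the latent target.
#' Total energy intake is a positive linear combination of all intakes plus
#' Gaussian noise, so that energy confounds every exposure; an independent
#' `energy_requirement` column supports energy-ratio trimming.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one column per exposure plus `energy_kcal` and
#'   `energy_requirement`; deterministic given `spec$seed`.
#' @export
#' @examples
#' ex <- generate_exposures(cohort_spec(200, n_foods = 4, n_nutrients = 2))
#' cor(ex$food_01, ex$energy_kcal)
generate_exposures <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants; m <- spec$m
  rho <- spec$exposure_correlation
  set.seed(split_seed(spec$seed, 1))

  block <- (seq_len(m) - 1) %/% spec$block_size + 1
  n_blocks <- max(block)
  shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
  idio <- matrix(rnorm(n * m), n, m)
  z <- sqrt(rho) * shared[, block, drop = FALSE] + sqrt(1 - rho) * idio

  # log-scale means spread across exposures so intakes span ~5-200 units/day
  mu <- log(seq(5, 200, length.out = m))
  intake <- exp(sweep(z * spec$latent_sd, 2, mu, "+"))
  colnames(intake) <- exposure_names(spec)

  # energy: each exposure contributes ~1200/m kcal in expectation
  loadings <- 1200 / (m * exp(mu + spec$latent_sd^2 / 2))
  energy <- 1200 + drop(intake %*% loadings) + rnorm(n, 0, spec$energy_noise_sd)
  energy <- pmax(energy, 500)
  requirement <- pmax(rnorm(n, 2400, 300), 800)

  out <- as.data.frame(intake)
  out$energy_kcal <- energy
  out$energy_requirement <- requirement
  out
}

#' Generate categorical confounders
#'
#' Draws the six categorical confounders of the default analysis model
#' (smoking, BMI category, physical activity, diabetes history, education,
#' family history) from the marginal distributions in the spec, with
#' optional independent missingness per confounder.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of character columns (missing values as `NA`).
#' @export
generate_confounders <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  set.seed(split_seed(spec$seed, 2))
  out <- lapply(CONFOUNDER_NAMES, function(nm) {
    p <- spec$confounder_probs[[nm]]
    x <- sample(names(p), n, replace = TRUE, prob = p)
    if (spec$missingness > 0)
      x[runif(n) < spec$missingness] <- NA_character_
    x
  })
  names(out) <- CONFOUNDER_NAMES
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate survival outcomes and assemble a cohort table
#'
#' Event ages are drawn from a Weibull proportional-hazards model on the age
#' time scale, conditional on being event-free at the (uniformly drawn)
#' entry age, with linear predictor built from the planted exposure effects
#' (per 1 SD of intake), the categorical confounder effects, total energy,
#' and a per-centre baseline offset. The linear predictor is centred at its
#' sample mean (centre offsets excluded) so the baseline calibration of the
#' spec is preserved. Follow-up is administratively censored at
#' `entry + admin_censor_years`. Subtype labels (stage, grade, PSA > 20
#' ng/mL, fatality) are drawn for events only; `aggressive` is derived as
#' advanced stage OR high grade OR PSA > 20 among known fields.
#'
#' @param exposures data.frame from [generate_exposures()].
#' @param confounders data.frame from [generate_confounders()].
#' @param spec a [cohort_spec()].
#' @return a cohort data.frame: `participant_id`, `age_entry`, `age_exit`,
#'   `event`, subtype columns (`stage`, `grade`, `psa_over_20`, `fatal`,
#'   `aggressive`), `center`, `age_band`, confounders, energy columns and
#'   exposures.
#' @export
generate_outcomes <- function(exposures, confounders, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  if (spec$admin_censor_years <= 0) stop("admin_censor_years must be positive")
  ex_names <- exposure_names(spec)
  if (!is.null(spec$planted_effects) &&
      !all(names(spec$planted_effects) %in% ex_names))
    stop("planted_effects name unknown exposures: ",
         paste(setdiff(names(spec$planted_effects), ex_names), collapse = ", "))

  set.seed(split_seed(spec$seed, 3))
  age_entry <- runif(n, spec$entry_age_min, spec$entry_age_max)
  center <- sprintf("center_%02d", sample.int(spec$n_centers, n, replace = TRUE))

  lp <- rep(0, n)
  for (nm in names(spec$planted_effects)) {
    x <- exposures[[nm]]
    lp <- lp + spec$planted_effects[[nm]] * (x - mean(x)) / sd(x)
  }
  for (nm in CONFOUNDER_NAMES) {
    eff <- spec$confounder_effects[[nm]]
    idx <- match(confounders[[nm]], names(spec$confounder_probs[[nm]]))
    contrib <- eff[idx]
    contrib[is.na(contrib)] <- 0  # missing confounder contributes baseline
    lp <- lp + contrib
  }
  lp <- lp + spec$energy_log_hr * exposures$energy_kcal
  lp <- lp - mean(lp)
  lp <- lp + spec$center_log_hr[match(center, sprintf("center_%02d",
                                                      seq_len(spec$n_centers)))]

  # conditional Weibull draw given event-free at entry (left truncation):
  # H(t) - H(a0) = E / exp(lp), E ~ Exp(1)
  k <- spec$baseline_shape; lam <- spec$baseline_scale
  e <- rexp(n)
  t_event <- lam * ((age_entry / lam)^k + e * exp(-lp))^(1 / k)
  t_censor <- age_entry + spec$admin_censor_years
  event <- as.integer(t_event <= t_censor)
  age_exit <- pmin(t_event, t_censor)

  stage <- grade <- psa <- rep(NA_character_, n)
  fatal <- rep(NA_integer_, n)
  idx <- which(event == 1)
  if (length(idx)) {
    sp <- spec$subtype_probs
    stage[idx] <- sample(names(sp$stage), length(idx), TRUE, prob = sp$stage)
    grade[idx] <- sample(names(sp$grade), length(idx), TRUE, prob = sp$grade)
    psa[idx] <- sample(names(sp$psa_over_20), length(idx), TRUE,
                       prob = sp$psa_over_20)
    fatal[idx] <- rbinom(length(idx), 1, sp$fatal)
  }
  aggressive <- ifelse(event == 1,
                       as.integer(stage == "advanced" | grade == "high" |
                                    psa == "yes"), NA_integer_)

  band_lo <- spec$entry_age_min +
    floor((age_entry - spec$entry_age_min) / spec$age_band_width) *
    spec$age_band_width
  age_band <- sprintf("age_%02d_%02d", as.integer(band_lo),
                      as.integer(band_lo + spec$age_band_width))

  cohort <- data.frame(
    participant_id = seq_len(n),
    age_entry = age_entry, age_exit = age_exit, event = event,
    stage = stage, grade = grade, psa_over_20 = psa, fatal = fatal,
    aggressive = aggressive,
    center = center, age_band = age_band,
    confounders,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, exposures)
  attr(cohort, "cohort_spec") <- spec
  cohort
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [generate_exposures()],
#' [generate_confounders()] and [generate_outcomes()] in sequence.
#'
#' @param spec a [cohort_spec()].
#' @return a cohort data.frame; see [generate_outcomes()].
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(1000, seed = 3))
#' mean(co$event)  # ~5% cumulative incidence under defaults
simulate_cohort <- function(spec) {
  ex <- generate_exposures(spec)
  cf <- generate_confounders(spec)
  generate_outcomes(ex, cf, spec)
}

#' Draw a case-cohort sample from a full cohort
#'
#' Emulates a case-cohort design: a simple random subcohort is drawn at
#' baseline and all cases are retained; non-case non-subcohort rows are
#' dropped. The result carries an `in_subcohort` 0/1 flag and is analysed
#' with [build_prentice_weights()] plus a robust-variance Cox fit.
#'
#' @param cohort a full cohort data.frame with an `event` column.
#' @param subcohort_fraction fraction of the cohort sampled into the
#'   subcohort, strictly between 0 and 1.
#' @param seed RNG seed for the subcohort draw.
#' @return the case-cohort data.frame.
#' @export
draw_case_cohort <- function(cohort, subcohort_fraction, seed = 1L) {
  if (!is.numeric(subcohort_fraction) || subcohort_fraction <= 0 ||
      subcohort_fraction >= 1)
    stop("subcohort_fraction must be strictly between 0 and 1")
  if (sum(cohort$event) == 0) stop("cohort contains no events")
  n <- nrow(cohort)
  set.seed(split_seed(seed, 4))
  sub_idx <- sample.int(n, size = round(subcohort_fraction * n))
  in_sub <- integer(n); in_sub[sub_idx] <- 1L
  keep <- in_sub == 1L | cohort$event == 1L
  out <- cohort[keep, , drop = FALSE]
  out$in_subcohort <- in_sub[keep]
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' Plain UTF-8 CSV with a header row and "." decimal separator; categorical
#' columns are stored as strings, missing values as empty fields.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE, na.strings = "",
           fileEncoding = "UTF-8")
}
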