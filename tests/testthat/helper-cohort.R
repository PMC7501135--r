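# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small spec: few exposures, everything else at package defaults
small_spec <- function(n, n_foods = 3, n_nutrients = 1, seed = 1, ...) {
  cohort_spec(n, n_foods = n_foods, n_nutrients = n_nutrients, seed = seed,
              ...)
}

# spec with every hazard effect silenced except what the caller plants:
# clean oracle conditions for calibration tests
null_effect_spec <- function(n, seed = 1, ...) {
  zero_effects <- list(
    smoking = c(0, 0, 0), bmi_cat = rep(0, 6), activity = rep(0, 4),
    diabetes = c(0, 0), education = rep(0, 4), family_history = c(0, 0))
  cohort_spec(n, seed = seed, confounder_effects = zero_effects,
              energy_log_hr = 0, center_log_hr = rep(0, 8), ...)
}

# minimal Cox model: exposure only, no strata or covariates
bare_cox_spec <- function(...) {
  cox_spec(strata = character(0), covariates = character(0), ...)
}

# lean screening model used in permutation-heavy calibration tests
lean_cox_spec <- function(...) {
  cox_spec(covariates = "energy_kcal", ...)
}

# coded default cohort shared by several survival tests
coded_cohort_5k <- function() {
  cached("coded5k", {
    spec <- small_spec(5000, seed = 42,
                       planted_effects = c(food_01 = log(1.2)))
    co <- simulate_cohort(spec)
    prepare_exposures(co, exposure_kinds(exposure_names(spec)))
  })
}

# 6-subject textbook data: alternating groups, no ties, finite MLE
toy_cox_data <- function() {
  data.frame(age_entry = 0, age_exit = 1:6, event = 1L,
             x = c(1, 0, 1, 0, 1, 0))
}

# 6-subject separated data: every exposed event precedes every unexposed
# one, so the partial-likelihood MLE is infinite
separated_cox_data <- function() {
  data.frame(age_entry = 0, age_exit = 1:6, event = 1L,
             x = c(1, 1, 1, 0, 0, 0))
}

# independent brute-force maximiser of the (tie-free) Cox partial
# likelihood for a single binary covariate
toy_partial_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# cause-specific competing-subtype cohort: exposure acts only on the
# high-grade cause
subtype_planted_cohort <- function(n, beta_high, seed) {
  set.seed(seed)
  x <- rnorm(n)
  h_high <- 0.02 * exp(beta_high * x)
  h_low <- 0.05
  t_high <- rexp(n) / h_high
  t_low <- rexp(n) / h_low
  t_event <- pmin(t_high, t_low)
  event <- as.integer(t_event <= 14)
  exit <- pmin(t_event, 14)
  grade <- ifelse(event == 1,
                  ifelse(t_high < t_low, "high", "low"), NA_character_)
  data.frame(participant_id = seq_len(n), age_entry = 50,
             age_exit = 50 + exit, event = event,
             stage = NA_character_, grade = grade,
             psa_over_20 = NA_character_, fatal = NA_integer_,
             aggressive = NA_integer_, x = x,
             stringsAsFactors = FALSE)
}

# independent step-up implementation of the Benjamini-Hochberg q-value
bh_bruteforce <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    candidates <- which(p >= p[i])
    min(1, min(m * p[candidates] / r[candidates]))
  }, numeric(1))
}

# independent transcription of the DerSimonian-Laird formulas
dl_bruteforce <- function(b, se) {
  w <- 1 / se^2
  bf <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bf)^2)
  df <- length(b) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * b) / sum(ws), se = sqrt(1 / sum(ws)),
       Q = Q, tau2 = tau2)
}

# brute-force counting implementation of the ratio FDR (per-factor mode,
# with step-up monotonization done by exhaustive minimum)
perm_fdr_bruteforce <- function(observed, null_mat) {
  m <- length(observed)
  raw <- vapply(seq_len(m), function(i) {
    t_i <- observed[i]
    null_prop <- sum(null_mat <= t_i) / length(null_mat)
    obs_prop <- sum(observed <= t_i) / m
    min(1, null_prop / obs_prop)
  }, numeric(1))
  vapply(seq_len(m), function(i)
    min(raw[observed >= observed[i]]), numeric(1))
}
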