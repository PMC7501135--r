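# Survival engine: partial-likelihood oracle equivalence, invariances,
# delayed entry, Prentice case-cohort weighting, PH diagnostics, subtype
# fits and heterogeneity tests.

test_that("fit_cox matches brute-force partial-likelihood maximization", {
  toy <- toy_cox_data()
  fit <- fit_cox(toy, "x", bare_cox_spec())
  oracle <- optimize(function(b) toy_partial_loglik(b, toy$age_exit,
                                                    toy$event, toy$x),
                     c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(fit$log_hr, oracle, tolerance = 1e-6)
  expect_true(fit$converged == 1)
  expect_identical(fit$n_events, 6L)
  # CI endpoints follow the Wald construction exactly
  z <- qnorm(0.975)
  expect_equal(fit$ci_low, exp(fit$log_hr - z * fit$se), tolerance = 1e-12)
  expect_equal(fit$ci_high, exp(fit$log_hr + z * fit$se), tolerance = 1e-12)
})

test_that("complete separation is flagged, not thrown", {
  fit <- fit_cox(separated_cox_data(), "x", bare_cox_spec())
  expect_identical(fit$converged, 0L)
})

test_that("unit weights, single stratum and tie methods are all no-ops", {
  co <- coded_cohort_5k()
  base <- suppressMessages(fit_cox(co, "food_02"))
  co$w1 <- 1
  weighted <- suppressMessages(
    fit_cox(co, "food_02", cox_spec(weights = "w1")))
  expect_identical(weighted$log_hr, base$log_hr)

  co$one_stratum <- "all"
  strat1 <- suppressMessages(
    fit_cox(co, "food_02", cox_spec(strata = "one_stratum")))
  unstrat <- suppressMessages(
    fit_cox(co, "food_02", cox_spec(strata = character(0))))
  expect_equal(strat1$log_hr, unstrat$log_hr, tolerance = 1e-12)

  # ages are continuous so there are no ties: Efron == Breslow
  efron <- suppressMessages(fit_cox(co, "food_02", cox_spec()))
  breslow <- suppressMessages(
    fit_cox(co, "food_02", cox_spec(tie_method = "breslow")))
  expect_equal(efron$log_hr, breslow$log_hr, tolerance = 1e-8)
})

test_that("reversing the exposure sign negates beta and mirrors the CI", {
  co <- coded_cohort_5k()
  f <- suppressMessages(fit_cox(co, "food_02"))
  co$food_02 <- -co$food_02
  g <- suppressMessages(fit_cox(co, "food_02"))
  expect_equal(g$log_hr, -f$log_hr, tolerance = 1e-8)
  expect_equal(g$ci_low, 1 / f$ci_high, tolerance = 1e-8)
  expect_equal(g$ci_high, 1 / f$ci_low, tolerance = 1e-8)
  expect_equal(g$p_value, f$p_value, tolerance = 1e-8)
})

test_that("a planted log hazard ratio is recovered", {
  co <- coded_cohort_5k()  # planted log(1.2) on food_01
  fit <- suppressMessages(fit_cox(co, "food_01"))
  expect_lt(abs(fit$log_hr - log(1.2)), 3 * fit$se)
  expect_gt(fit$n_events, 100)
})

test_that("Wald p-values are calibrated under the null", {
  ps <- vapply(1:100, function(i) {
    co <- simulate_cohort(null_effect_spec(400, seed = 1000 + i,
                                           n_foods = 1, n_nutrients = 0))
    co$food_01 <- zscore(co$food_01)
    suppressMessages(fit_cox(co, "food_01", bare_cox_spec()))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("sandwich and model SEs agree on correctly-specified data", {
  co <- coded_cohort_5k()
  rob <- suppressMessages(
    fit_cox(co, "food_01", cox_spec(robust_variance = TRUE)))
  expect_lt(abs(rob$robust_se - rob$se) / rob$se, 0.10)
})

test_that("zero-variance exposures and unknown columns are rejected", {
  co <- coded_cohort_5k()
  co$flat <- 1
  expect_error(suppressMessages(fit_cox(co, "flat")), "zero variance")
  expect_error(fit_cox(co, "missing_col"), "not found")
})

test_that("Prentice weighting degenerates to the ordinary fit when the
          subcohort is the whole cohort", {
  co <- coded_cohort_5k()
  co$in_subcohort <- 1L
  w <- build_prentice_weights(co)
  wfit <- suppressMessages(
    fit_cox(w, "food_01", cox_spec(weights = "prentice_weight",
                                   robust_variance = TRUE)))
  full <- suppressMessages(fit_cox(co, "food_01"))
  expect_equal(wfit$log_hr, full$log_hr, tolerance = 1e-8)
})

test_that("Prentice entry offset is insensitive to halving", {
  co <- coded_cohort_5k()
  cc <- draw_case_cohort(co, 0.2, seed = 8)
  eps <- 1e-5 * (max(cc$age_exit) - min(cc$age_entry))
  spec <- cox_spec(weights = "prentice_weight", robust_variance = TRUE)
  f1 <- suppressMessages(fit_cox(build_prentice_weights(cc, eps), "food_01",
                                 spec))
  f2 <- suppressMessages(fit_cox(build_prentice_weights(cc, eps / 2),
                                 "food_01", spec))
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-8)
})

test_that("an inconsistent case-cohort file is rejected", {
  co <- coded_cohort_5k()
  cc <- draw_case_cohort(co, 0.1, seed = 9)
  cc$in_subcohort[which(cc$event == 0)[1]] <- 0L
  expect_error(build_prentice_weights(cc), "inconsistent case-cohort")
})

test_that("the Schoenfeld slope test is calibrated under proportional
          hazards and powered against a sign-flipping effect", {
  rejections <- vapply(1:200, function(i) {
    co <- simulate_cohort(null_effect_spec(
      300, seed = 2000 + i, n_foods = 1, n_nutrients = 0,
      planted_effects = c(food_01 = 0.3)))
    co$food_01 <- zscore(co$food_01)
    fit <- suppressMessages(fit_cox(co, "food_01", bare_cox_spec()))
    schoenfeld_test(fit)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))

  # beta(t) flips sign mid-follow-up: strong violation, high rejection rate
  flips <- vapply(1:10, function(i) {
    set.seed(3000 + i)
    n <- 2000; x <- rnorm(n); beta <- 0.8; h0 <- 0.15; t0 <- 5
    u <- rexp(n)
    t1 <- u / (h0 * exp(beta * x))
    t_ev <- ifelse(t1 < t0, t1,
                   t0 + (u - h0 * exp(beta * x) * t0) / (h0 * exp(-beta * x)))
    d <- data.frame(age_entry = 0, age_exit = pmin(t_ev, 10),
                    event = as.integer(t_ev <= 10), x = x)
    fit <- suppressMessages(fit_cox(d, "x", bare_cox_spec()))
    schoenfeld_test(fit)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(flips), 0.8)

  # fewer than 2 events is an error
  one_ev <- data.frame(age_entry = 0, age_exit = c(1, 2, 3),
                       event = c(1L, 0L, 0L), x = c(0.5, -1, 0.2))
  fit1 <- suppressMessages(fit_cox(one_ev, "x", bare_cox_spec()))
  expect_error(schoenfeld_test(fit1), "2 events")
})

test_that("subtype fits define cause-specific outcomes correctly", {
  co <- coded_cohort_5k()
  # all events recoded to the target subtype: identical to the total fit
  co2 <- co
  co2$grade[co2$event == 1] <- "low"
  total <- suppressMessages(fit_cox(co2, "food_01"))
  low <- suppressMessages(fit_subtype(co2, "food_01", "low_grade"))
  expect_equal(low$log_hr, total$log_hr, tolerance = 1e-12)
  expect_identical(low$n_events, total$n_events)

  expect_error(suppressMessages(
    fit_subtype(co2, "food_01", "high_grade")), "no events")
  expect_error(fit_subtype(co, "food_01", "nonsense"))
})

test_that("an effect planted on one subtype is recovered there and absent
          elsewhere", {
  d <- subtype_planted_cohort(10000, beta_high = log(1.5), seed = 41)
  high <- suppressMessages(fit_subtype(d, "x", "high_grade", bare_cox_spec()))
  low <- suppressMessages(fit_subtype(d, "x", "low_grade", bare_cox_spec()))
  expect_lt(abs(high$log_hr - log(1.5)), 3 * high$se)
  expect_lt(abs(low$log_hr), 3 * low$se)
})

test_that("randomly reassigned subtype labels give homogeneous fits", {
  co <- coded_cohort_5k()
  set.seed(55)
  ev <- which(co$event == 1)
  co$stage[ev] <- sample(c("localized", "advanced"), length(ev),
                         replace = TRUE)
  loc <- suppressMessages(fit_subtype(co, "food_01", "localized"))
  adv <- suppressMessages(fit_subtype(co, "food_01", "advanced"))
  het <- wald_heterogeneity(loc, adv, "stage")
  expect_gt(het$p_value, 0.001)
})

test_that("the heterogeneity z-test matches hand arithmetic", {
  mk <- function(b, se) structure(list(log_hr = b, se_used = se,
                                       subtype_outcome = "s"),
                                  class = "cox_fit")
  same <- wald_heterogeneity(mk(0.1, 0.05), mk(0.1, 0.07))
  expect_equal(same$p_value, 1)

  # back-transformed published CIs: 0.98 (0.94-1.02) vs 1.09 (1.03-1.15)
  b1 <- log(0.98); se1 <- (log(1.02) - log(0.94)) / (2 * 1.96)
  b2 <- log(1.09); se2 <- (log(1.15) - log(1.03)) / (2 * 1.96)
  het <- wald_heterogeneity(mk(b1, se1), mk(b2, se2))
  z_hand <- (b1 - b2) / sqrt(se1^2 + se2^2)
  expect_equal(het$statistic, z_hand, tolerance = 1e-6)
  expect_equal(het$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-6)

  expect_error(wald_heterogeneity(mk(0.1, NA), mk(0.1, 0.1)),
               "standard errors")
})

test_that("heterogeneity p-values are calibrated when subtype effects are
          equal", {
  set.seed(66)
  ps <- vapply(1:50, function(i) {
    b <- rnorm(2, 0.1, 0.04)  # equal true effect, independent noise
    mk <- function(b, se) structure(list(log_hr = b, se_used = se),
                                    class = "cox_fit")
    wald_heterogeneity(mk(b[1], 0.04), mk(b[2], 0.04))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
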