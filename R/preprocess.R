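# Data preparation: exclusion cascades with audit, energy-ratio trimming,
# residual-method energy adjustment, standardization, quartile coding.

#' Apply an ordered exclusion cascade with an audit trail
#'
#' Rows are removed by a sequence of logical flag columns applied in order; a
#' row failing several rules is counted against the first rule that removes
#' it, matching how exclusion cascades are reported in cohort papers.
#'
#' @param roster data.frame with one logical (or 0/1) flag column per rule;
#'   `TRUE`/1 means "exclude".
#' @param rules character vector of flag column names, in reporting order.
#'   Names of the vector, if any, are used as rule labels in the audit.
#' @return list with `cohort` (the retained rows) and `audit`, an
#'   `exclusion_audit` object recording `initial_n`, per-step sequential
#'   removals and `final_n`.
#' @export
#' @examples
#' roster <- data.frame(x = 1:10, bad = c(rep(TRUE, 3), rep(FALSE, 7)))
#' apply_exclusions(roster, c("prevalent disease" = "bad"))$audit
apply_exclusions <- function(roster, rules) {
  missing_cols <- setdiff(unname(rules), names(roster))
  if (length(missing_cols))
    stop("unknown exclusion flag column(s): ",
         paste(missing_cols, collapse = ", "))
  labels <- if (is.null(names(rules))) unname(rules) else
    ifelse(names(rules) == "", unname(rules), names(rules))
  initial_n <- nrow(roster)
  alive <- rep(TRUE, initial_n)
  removed <- integer(length(rules))
  for (k in seq_along(rules)) {
    flag <- as.logical(roster[[rules[[k]]]])
    flag[is.na(flag)] <- FALSE
    hit <- alive & flag
    removed[k] <- sum(hit)
    alive <- alive & !hit
  }
  audit <- structure(
    list(initial_n = initial_n,
         steps = data.frame(rule = labels, n_removed = removed,
                            stringsAsFactors = FALSE),
         final_n = sum(alive)),
    class = "exclusion_audit")
  list(cohort = roster[alive, , drop = FALSE], audit = audit)
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat(sprintf("Exclusion cascade: %d -> %d participants\n",
              x$initial_n, x$final_n))
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  - %s: %d removed\n", x$steps$rule[i], x$steps$n_removed[i]))
  invisible(x)
}

#' Build a roster reproducing a published exclusion cascade
#'
#' Given an initial roster size and ordered per-rule removal counts (as
#' printed in a cohort paper's flow diagram), constructs a roster
#' data.frame with one logical flag column per rule such that applying
#' [apply_exclusions()] in the printed order removes exactly the printed
#' number of rows at each step. Because cascade counts are sequential, the
#' flags are set on disjoint row blocks.
#'
#' @param initial_n roster size before exclusions.
#' @param counts named integer vector of per-rule removals, in cascade
#'   order.
#' @return data.frame with `participant_id` and one flag column per rule.
#' @export
#' @examples
#' roster <- exclusion_roster(100, c(rule_a = 10, rule_b = 5))
#' apply_exclusions(roster, setNames(names(counts <- c(rule_a = 10,
#'   rule_b = 5)), names(counts)))$audit$final_n  # 85
exclusion_roster <- function(initial_n, counts) {
  if (sum(counts) > initial_n)
    stop("removal counts exceed the roster size")
  roster <- data.frame(participant_id = seq_len(initial_n))
  offset <- 0
  for (nm in names(counts)) {
    flag <- rep(FALSE, initial_n)
    if (counts[[nm]] > 0)
      flag[offset + seq_len(counts[[nm]])] <- TRUE
    roster[[nm]] <- flag
    offset <- offset + counts[[nm]]
  }
  roster
}

#' Flag extreme energy intake-to-requirement ratios
#'
#' Flags rows in the bottom `lower_pct`\% or top `upper_pct`\% of the
#' empirical distribution of `energy_kcal / energy_requirement`, the usual
#' screen for implausible dietary reporting. Percentiles are order
#' statistics: with `n` rows and lower percentage `p`, exactly
#' `floor(n * p / 100)` rows are flagged at each end, except that a tie
#' spanning the cut is conservatively NOT flagged (so a constant ratio flags
#' nothing).
#'
#' @param cohort data.frame with positive `energy_kcal` and
#'   `energy_requirement` columns.
#' @param lower_pct,upper_pct percentages (defaults 1 and 1).
#' @return logical vector, `TRUE` for rows to exclude.
#' @export
flag_extreme_energy_ratio <- function(cohort, lower_pct = 1, upper_pct = 1) {
  if (is.null(cohort$energy_kcal) || is.null(cohort$energy_requirement))
    stop("cohort must contain energy_kcal and energy_requirement")
  if (any(cohort$energy_requirement <= 0))
    stop("energy_requirement must be positive")
  ratio <- cohort$energy_kcal / cohort$energy_requirement
  n <- length(ratio)
  k_lo <- floor(n * lower_pct / 100)
  k_hi <- floor(n * upper_pct / 100)
  # ties.method = "max": a tie group straddling the cut gets rank > k, so it
  # is left unflagged (conservative, deterministic)
  low <- rank(ratio, ties.method = "max") <= k_lo
  high <- rank(-ratio, ties.method = "max") <= k_hi
  low | high
}

#' Energy-adjust a nutrient intake by the residual method
#'
#' Replaces a nutrient intake by its residual from the least-squares
#' regression of intake on total energy, plus the predicted intake at the
#' mean energy (which for simple OLS is the mean intake), so units are
#' preserved. The adjusted intake has exactly zero sample correlation with
#' energy, removing confounding by total energy intake.
#'
#' @param intake numeric vector of nutrient intakes.
#' @param energy numeric vector of total energy intakes (same length,
#'   non-degenerate).
#' @return numeric vector of energy-adjusted intakes.
#' @export
#' @examples
#' residual_energy_adjust(c(10, 12, 14, 13, 16),
#'                        c(2000, 2100, 2200, 2300, 2400))
residual_energy_adjust <- function(intake, energy) {
  if (length(intake) != length(energy))
    stop("intake and energy must have the same length")
  if (sd(energy) == 0) stop("energy has zero variance")
  fit <- lm(intake ~ energy)
  unname(residuals(fit) + coef(fit)[1] + coef(fit)[2] * mean(energy))
}

#' Standardize to zero mean and unit standard deviation
#'
#' Uses the sample (n - 1 denominator) standard deviation, so downstream
#' hazard ratios are per 1 SD of intake.
#'
#' @param x numeric vector with positive variance.
#' @return standardized numeric vector.
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Code a continuous exposure into sample quartiles
#'
#' Categories are defined by the 25th/50th/75th sample percentiles
#' (`quantile()` type 7); values equal to a boundary go to the lower
#' category. With heavy ties the category sizes are unequal but category is
#' monotone in value.
#'
#' @param x numeric vector, length at least 4, with at least 4 distinct
#'   values.
#' @return integer vector of quartile codes 1-4.
#' @export
#' @examples
#' quartile_code(1:8)
quartile_code <- function(x) {
  if (length(x) < 4) stop("need at least 4 observations")
  if (length(unique(x)) < 4) stop("need at least 4 distinct values")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  1L + (x > q[1]) + (x > q[2]) + (x > q[3])
}

#' Apply the study coding to every exposure column
#'
#' Nutrient exposures are energy-adjusted by the residual method and then
#' standardized; food exposures are standardized raw (total energy stays in
#' the model as a covariate). With `coding = "quartile"` exposures are
#' instead coded into sample quartiles (the sensitivity analysis).
#'
#' @param cohort cohort data.frame containing the exposure columns and
#'   `energy_kcal`.
#' @param kinds named character vector mapping exposure column names to
#'   `"food"` or `"nutrient"`; see [exposure_kinds()].
#' @param coding `"zscore"` (default) or `"quartile"`.
#' @return the cohort with exposure columns recoded; the applied coding is
#'   recorded in `attr(, "exposure_coding")`.
#' @export
prepare_exposures <- function(cohort, kinds, coding = c("zscore", "quartile")) {
  coding <- match.arg(coding)
  missing_cols <- setdiff(names(kinds), names(cohort))
  if (length(missing_cols))
    stop("exposure column(s) not in cohort: ",
         paste(missing_cols, collapse = ", "))
  for (nm in names(kinds)) {
    x <- cohort[[nm]]
    if (kinds[[nm]] == "nutrient")
      x <- residual_energy_adjust(x, cohort$energy_kcal)
    cohort[[nm]] <- if (coding == "zscore") zscore(x) else quartile_code(x)
  }
  attr(cohort, "exposure_coding") <- coding
  cohort
}
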