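# The exposure-wide screen and its multiplicity correction: one Cox fit per
# exposure x outcome, a permutation-constructed null distribution of
# p-values, the ratio false discovery rate, Benjamini-Hochberg q-values and
# the replication selection rule.

#' Screen every exposure against one or more outcomes
#'
#' Fits the screening Cox model of [fit_cox()] (via [fit_subtype()] when the
#' outcome is a disease subtype) once per exposure and outcome. Fits that
#' fail to converge are retained with `converged = 0` rather than aborting
#' the screen.
#'
#' @param cohort cohort data.frame with coded exposures (see
#'   [prepare_exposures()]).
#' @param exposures character vector of exposure column names.
#' @param spec a [cox_spec()].
#' @param outcomes character vector of outcomes (see [fit_subtype()]);
#'   default `"total"`.
#' @param kinds optional named kind vector (see [exposure_kinds()]); defaults
#'   to kinds inferred from the names.
#' @return a `screen_table` data.frame: one row per exposure x outcome with
#'   `exposure`, `kind`, `outcome`, `log_hr`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `n_events`, `converged`.
#' @export
run_screen <- function(cohort, exposures, spec = cox_spec(),
                       outcomes = "total", kinds = NULL) {
  if (length(exposures) == 0) stop("empty exposure list")
  if (anyDuplicated(exposures)) stop("duplicate exposure names")
  if (is.null(kinds)) kinds <- exposure_kinds(exposures)
  rows <- list()
  for (oc in outcomes) {
    for (ex in exposures) {
      fit <- suppressMessages(fit_subtype(cohort, ex, oc, spec))
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = ex, kind = unname(kinds[[ex]]), outcome = oc,
        log_hr = fit$log_hr, se = fit$se_used, hr = fit$hr,
        ci_low = fit$ci_low, ci_high = fit$ci_high,
        p_value = fit$p_value, n_events = fit$n_events,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Permute outcomes to build one null replicate
#'
#' Jointly permutes the outcome across participants: the pairs (event
#' indicator, follow-up duration) — together with the subtype labels that
#' belong to the event — are shuffled as a unit, while exposures,
#' confounders, strata and entry ages stay put. Exit age is reconstructed
#' as entry age plus the permuted duration, so the multiset of follow-up
#' durations and the number of events are preserved exactly and any
#' exposure-outcome association is destroyed.
#'
#' @param cohort cohort data.frame.
#' @param seed RNG seed for this permutation.
#' @return the permuted cohort.
#' @export
permute_outcomes <- function(cohort, seed) {
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort")
  set.seed(split_seed(seed, 5))
  perm <- sample.int(n)
  duration <- cohort$age_exit - cohort$age_entry
  cohort$event <- cohort$event[perm]
  cohort$age_exit <- cohort$age_entry + duration[perm]
  for (col in intersect(c("stage", "grade", "psa_over_20", "fatal",
                          "aggressive"), names(cohort)))
    cohort[[col]] <- cohort[[col]][perm]
  cohort
}

#' Build the permutation null distribution of p-values
#'
#' For `b = 1..B`, permutes the outcome with [permute_outcomes()] under a
#' child seed derived from `seed`, refits every exposure with the screening
#' model, and stores the Wald p-values. A refit that fails (error or
#' non-convergence) contributes `p = 1`, which can only inflate — never
#' deflate — the resulting FDR.
#'
#' @param cohort cohort data.frame with coded exposures.
#' @param exposures character vector of exposure columns.
#' @param spec a [cox_spec()].
#' @param B number of permutations (at least 1).
#' @param seed master seed for the permutation stream.
#' @param outcome outcome passed to the screen (default `"total"`).
#' @return object of class `null_pvalues`: list with `B`, `seed`, `outcome`
#'   and `matrix`, the B x m matrix of null p-values (columns named by
#'   exposure).
#' @export
build_null <- function(cohort, exposures, spec = cox_spec(), B = 100,
                       seed = 1L, outcome = "total") {
  if (B < 1) stop("B must be at least 1")
  m <- length(exposures)
  mat <- matrix(NA_real_, B, m, dimnames = list(NULL, exposures))
  for (b in seq_len(B)) {
    permuted <- permute_outcomes(cohort, seed = split_seed(seed, 100 + b))
    for (j in seq_len(m)) {
      p <- tryCatch({
        fit <- suppressMessages(fit_subtype(permuted, exposures[j], outcome,
                                            spec))
        if (fit$converged && is.finite(fit$p_value)) fit$p_value else 1
      }, error = function(e) {
        warning("permuted refit failed for ", exposures[j],
                " (b = ", b, "); recording p = 1", call. = FALSE)
        1
      })
      mat[b, j] <- p
    }
  }
  structure(list(B = B, seed = seed, outcome = outcome, matrix = mat),
            class = "null_pvalues")
}

#' Permutation-based false discovery rate (ratio method)
#'
#' For each exposure, the FDR is the ratio of the proportion of null
#' (permuted-outcome) p-values at or below a significance threshold to the
#' proportion of observed p-values at or below it, capped at 1. Two
#' thresholding modes are available:
#'
#' * `"per_factor"` (default): the threshold for exposure `i` is its own
#'   observed p-value, giving each factor its own FDR estimate; the ratios
#'   are then monotonized step-up style (each exposure receives the
#'   smallest ratio achievable at any threshold at least its own p-value),
#'   so a smaller observed p never carries a larger FDR.
#' * `"fixed"`: a single threshold `alpha` (the 5\% level of the original
#'   ratio definition) shared by all exposures.
#'
#' Benjamini-Hochberg q-values are included alongside as the standard
#' sensitivity analysis, and exposures with permutation FDR below
#' `select_threshold` are flagged for replication.
#'
#' @param observed named numeric vector of observed p-values (one per
#'   exposure), or a `screen_table` from [run_screen()] restricted to one
#'   outcome.
#' @param null a `null_pvalues` object from [build_null()].
#' @param mode `"per_factor"` or `"fixed"`.
#' @param alpha threshold used when `mode = "fixed"` (default 0.05).
#' @param select_threshold FDR cutoff for the replication flag (default
#'   0.05; selection uses a strict `<`).
#' @return an `fdr_table` data.frame: `exposure`, `observed_p`, `perm_fdr`,
#'   `bh_q`, `selected_for_replication`.
#' @export
permutation_fdr <- function(observed, null, mode = c("per_factor", "fixed"),
                            alpha = 0.05, select_threshold = 0.05) {
  mode <- match.arg(mode)
  if (inherits(observed, "screen_table") || is.data.frame(observed)) {
    if (length(unique(observed$outcome)) > 1)
      stop("restrict the screen table to a single outcome before computing FDR")
    observed <- setNames(observed$p_value, observed$exposure)
  }
  if (!inherits(null, "null_pvalues")) stop("null must come from build_null()")
  mat <- null$matrix
  if (ncol(mat) != length(observed))
    stop("null matrix has ", ncol(mat), " exposures but ", length(observed),
         " observed p-values were supplied")
  if (nrow(mat) < 1) stop("empty null distribution")
  m <- length(observed)
  thresholds <- if (mode == "per_factor") observed else rep(alpha, m)
  fdr <- vapply(seq_len(m), function(i) {
    t_i <- thresholds[i]
    null_prop <- mean(mat <= t_i)
    obs_prop <- mean(observed <= t_i)  # >= 1/m always in per_factor mode
    if (obs_prop == 0) return(1)
    min(null_prop / obs_prop, 1)
  }, numeric(1))
  if (mode == "per_factor") {
    # step-up monotonization (as in q-value estimators): each exposure gets
    # the smallest ratio achievable at any threshold >= its own p-value, so
    # a smaller observed p never carries a larger FDR
    ord <- order(observed, decreasing = TRUE)
    fdr[ord] <- cummin(fdr[ord])
  }
  out <- data.frame(exposure = names(observed), observed_p = unname(observed),
                    perm_fdr = fdr, bh_q = bh_fdr(unname(observed)),
                    stringsAsFactors = FALSE)
  out$selected_for_replication <- as.integer(out$perm_fdr < select_threshold)
  rownames(out) <- NULL
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values: `q_i = min over {j : p_j >= p_i} of (m * p_j / rank_j)`,
#' capped at 1 and monotone in p. Delegates to `p.adjust(method = "BH")`
#' after validating the input range.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Select exposures for replication
#'
#' Exposures whose permutation FDR is strictly below the threshold, ordered
#' by FDR (ties broken by observed p-value).
#'
#' @param fdr_table an `fdr_table` from [permutation_fdr()].
#' @param threshold FDR cutoff (default 0.05).
#' @return character vector of exposure names (possibly empty).
#' @export
select_for_replication <- function(fdr_table, threshold = 0.05) {
  stopifnot(is.data.frame(fdr_table), !is.null(fdr_table$perm_fdr))
  hit <- fdr_table[fdr_table$perm_fdr < threshold, , drop = FALSE]
  hit <- hit[order(hit$perm_fdr, hit$observed_p), , drop = FALSE]
  hit$exposure
}
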