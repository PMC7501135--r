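# DerSimonian-Laird random-effects pooling of cohort-specific log hazard
# ratios, including pooling directly from published HR + CI pairs.

#' Convert a hazard ratio and confidence interval to the log scale
#'
#' `log_hr = log(hr)`; `se = (log(ci_high) - log(ci_low)) / (2 * z)` with
#' `z` the normal quantile for `ci_level`. When back-computing from results
#' printed in a journal, `z = 1.96` (the value used in most published
#' tables) can be requested explicitly; the default is the exact quantile
#' `qnorm(0.975) = 1.959964...`.
#'
#' @param hr hazard ratio, with `0 < ci_low <= hr <= ci_high`.
#' @param ci_low,ci_high confidence limits (strictly `ci_low < ci_high`).
#' @param ci_level confidence level of the interval (default 0.95).
#' @param z optional explicit normal quantile overriding `ci_level`.
#' @return list with `log_hr` and `se`.
#' @export
#' @examples
#' log_scale_from_ci(2.0, 1.0, 4.0)
log_scale_from_ci <- function(hr, ci_low, ci_high, ci_level = 0.95, z = NULL) {
  if (!(ci_low > 0 && ci_low <= hr && hr <= ci_high))
    stop("need 0 < ci_low <= hr <= ci_high")
  if (ci_low == ci_high) stop("zero-width confidence interval")
  if (is.null(z)) z <- qnorm(1 - (1 - ci_level) / 2)
  list(log_hr = log(hr), se = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Assemble study estimates for meta-analysis
#'
#' Either supply `log_hr` and `se` directly, or supply published `hr`,
#' `ci_low`, `ci_high` to be converted with [log_scale_from_ci()].
#'
#' @param label character vector of study labels.
#' @param log_hr,se log hazard ratios and standard errors (direct route).
#' @param hr,ci_low,ci_high published estimates (converted route).
#' @param ci_level,z passed to [log_scale_from_ci()].
#' @return data.frame of class `study_estimates` with `label`, `log_hr`,
#'   `se`.
#' @export
#' @examples
#' study_estimates(c("discovery", "replication"),
#'                 hr = c(1.07, 1.09), ci_low = c(1.03, 1.02),
#'                 ci_high = c(1.11, 1.16), z = 1.96)
study_estimates <- function(label, log_hr = NULL, se = NULL,
                            hr = NULL, ci_low = NULL, ci_high = NULL,
                            ci_level = 0.95, z = NULL) {
  if (is.null(log_hr)) {
    conv <- Map(log_scale_from_ci, hr, ci_low, ci_high,
                MoreArgs = list(ci_level = ci_level, z = z))
    log_hr <- vapply(conv, `[[`, numeric(1), "log_hr")
    se <- vapply(conv, `[[`, numeric(1), "se")
  }
  if (any(se <= 0)) stop("standard errors must be positive")
  out <- data.frame(label = label, log_hr = log_hr, se = se,
                    stringsAsFactors = FALSE)
  class(out) <- c("study_estimates", "data.frame")
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools two or more study-specific log hazard ratios. Fixed-effect weights
#' `w_i = 1/se_i^2` give the Cochran heterogeneity statistic
#' `Q = sum w_i (b_i - b_fixed)^2`; the between-study variance is the
#' moment estimator `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`;
#' random-effects weights are `1/(se_i^2 + tau2)`. With `tau2 = 0` the
#' random-effects result coincides with the fixed-effect one.
#'
#' @param estimates a `study_estimates` data.frame (or any data.frame with
#'   `label`, `log_hr`, `se`), at least 2 rows.
#' @param ci_level confidence level (default 0.95).
#' @param method `"random_effects"` (default) or `"fixed_effect"`.
#' @return object of class `meta_result`: `pooled_log_hr`, `pooled_se`,
#'   `pooled_hr`, `ci_low`, `ci_high`, `Q`, `df`, `tau2`, `method`, `k`,
#'   and the input `estimates`.
#' @export
#' @examples
#' est <- study_estimates(c("A", "B"), hr = c(1.07, 1.09),
#'                        ci_low = c(1.03, 1.02), ci_high = c(1.11, 1.16),
#'                        z = 1.96)
#' dl_meta(est)
dl_meta <- function(estimates, ci_level = 0.95,
                    method = c("random_effects", "fixed_effect")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(estimates),
            all(c("label", "log_hr", "se") %in% names(estimates)))
  if (nrow(estimates) < 2) stop("at least 2 studies are required")
  if (any(estimates$se <= 0)) stop("standard errors must be positive")
  b <- estimates$log_hr; se <- estimates$se
  w <- 1 / se^2
  b_fixed <- sum(w * b) / sum(w)
  df <- length(b) - 1L
  Q <- sum(w * (b - b_fixed)^2)
  tau2 <- if (method == "fixed_effect") 0 else
    max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * b) / sum(w_star)
  pooled_se <- 1 / sqrt(sum(w_star))
  z <- qnorm(1 - (1 - ci_level) / 2)
  structure(list(
    pooled_log_hr = pooled, pooled_se = pooled_se,
    pooled_hr = exp(pooled),
    ci_low = exp(pooled - z * pooled_se),
    ci_high = exp(pooled + z * pooled_se),
    ci_level = ci_level,
    Q = Q, df = df, tau2 = tau2, method = method, k = length(b),
    estimates = estimates),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s meta-analysis of %d studies\n",
              if (x$method == "random_effects") "Random-effects (DerSimonian-Laird)"
              else "Fixed-effect", x$k))
  cat(sprintf("  pooled HR %.4f (%.0f%% CI %.4f-%.4f)\n",
              x$pooled_hr, 100 * x$ci_level, x$ci_low, x$ci_high))
  cat(sprintf("  Q = %.4f on %d df, tau^2 = %.6f\n", x$Q, x$df, x$tau2))
  invisible(x)
}

#' Read study estimates from a CSV or JSON file
#'
#' CSV columns (or JSON fields): `label`, and either `log_hr` + `se` or
#' `hr` + `ci_low` + `ci_high`.
#'
#' @param path file path (extension decides the format).
#' @param z optional normal quantile for CI back-conversion (e.g. 1.96 for
#'   published tables).
#' @return a `study_estimates` data.frame.
#' @export
read_study_estimates <- function(path, z = NULL) {
  if (!file.exists(path)) stop("study estimates file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path)) else
      read.csv(path, stringsAsFactors = FALSE)
  if (all(c("log_hr", "se") %in% names(df)))
    study_estimates(df$label, log_hr = df$log_hr, se = df$se)
  else
    study_estimates(df$label, hr = df$hr, ci_low = df$ci_low,
                    ci_high = df$ci_high, z = z)
}
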