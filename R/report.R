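# Reporting tables: volcano-plot and forest-plot data, as plain data.frames
# ready for CSV export or plotting.

#' Volcano-plot table for a screen
#'
#' One row per exposure: the hazard ratio per 1 SD on the x axis and
#' `-log10` of the FDR-adjusted p-value on the y axis, with a significance
#' flag at the replication threshold. An FDR capped at 1 maps to y = 0.
#'
#' @param screen a `screen_table` from [run_screen()] (single outcome).
#' @param fdr an `fdr_table` from [permutation_fdr()] over the same
#'   exposures.
#' @param threshold significance threshold drawn on the plot (default 0.05).
#' @return data.frame with `exposure`, `kind`, `hr`, `fdr`,
#'   `neg_log10_fdr`, `significant`.
#' @export
volcano_table <- function(screen, fdr, threshold = 0.05) {
  if (!setequal(screen$exposure, fdr$exposure))
    stop("screen and FDR tables cover different exposures")
  if (length(unique(screen$outcome)) > 1)
    stop("restrict the screen table to a single outcome")
  merged <- merge(screen[, c("exposure", "kind", "hr")],
                  fdr[, c("exposure", "perm_fdr")], by = "exposure")
  out <- data.frame(exposure = merged$exposure, kind = merged$kind,
                    hr = merged$hr, fdr = merged$perm_fdr,
                    neg_log10_fdr = -log10(merged$perm_fdr),
                    significant = as.integer(merged$perm_fdr < threshold),
                    stringsAsFactors = FALSE)
  out[order(out$exposure), , drop = FALSE]
}

#' Forest-plot table for a meta-analysis
#'
#' One row per study plus a pooled row, all on the hazard-ratio scale.
#'
#' @param meta a `meta_result` from [dl_meta()].
#' @return data.frame with `label`, `hr`, `ci_low`, `ci_high`, `weight_pct`
#'   (random-effects weights, summing to 100 over the studies) and `pooled`
#'   flag.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  est <- meta$estimates
  z <- qnorm(1 - (1 - meta$ci_level) / 2)
  w_star <- 1 / (est$se^2 + meta$tau2)
  rbind(
    data.frame(label = est$label,
               hr = exp(est$log_hr),
               ci_low = exp(est$log_hr - z * est$se),
               ci_high = exp(est$log_hr + z * est$se),
               weight_pct = 100 * w_star / sum(w_star),
               pooled = 0L, stringsAsFactors = FALSE),
    data.frame(label = sprintf("Pooled (%s)", meta$method),
               hr = meta$pooled_hr, ci_low = meta$ci_low,
               ci_high = meta$ci_high, weight_pct = 100, pooled = 1L,
               stringsAsFactors = FALSE))
}
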