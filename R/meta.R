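# Fixed-effect inverse-variance pooling of study unit values, with
# standard-error imputation for studies that report only an interval or no
# uncertainty at all.
#
# Imputation rules, applied on the relative (percentage) scale and carried
# multiplicatively onto the base-year unit-value scale (every transfer step
# is linear, so relative SEs are preserved):
#   interval (lo, hi)  -> the bounds are read as a 95% confidence interval of
#                         a normal premium, so rel SE = ((hi-lo)/(2*1.96)) /
#                         midpoint
#   none               -> rel SE = 0.5 (SE is half the point estimate)
#   reported-se        -> the study's own relative SE is used as-is

#' Impute a standard error for a unit-value estimate
#'
#' @param record a [hedonic_study()] (supplies the uncertainty kind and, for
#'   intervals, the premium bounds).
#' @param point_effect the study's unit value Y_g (EUR/m2/household/yr), > 0.
#' @return SE_g on the unit-value scale.
#' @export
impute_se <- function(record, point_effect) {
  gw_check_number(point_effect, "point_effect", min = 0, strict = TRUE)
  rel <- switch(record$uncertainty,
    "interval" = {
      if (record$premium_hi <= record$premium_lo) {
        gw_stop(sprintf("study %s: degenerate interval (lo == hi) would give a zero SE and infinite weight",
                        record$study_id), "gwcba_zero_se")
      }
      ((record$premium_hi - record$premium_lo) / (2 * 1.96)) / premium_midpoint(record)
    },
    "none" = 0.5,
    "reported-se" = record$rel_se
  )
  if (!is.finite(rel) || rel <= 0) {
    gw_stop(sprintf("study %s: imputed relative SE is not positive", record$study_id),
            "gwcba_zero_se")
  }
  rel * point_effect
}

#' Build weighted estimates from study records
#'
#' Runs the transfer chain for each record, imputes its SE and attaches the
#' inverse-variance weight W_g = 1/SE_g^2.
#'
#' @param studies list of [hedonic_study()] records.
#' @param config a [transfer_config()].
#' @return A data.frame with columns `study_id`, `effect`, `se`, `variance`,
#'   `weight`.
#' @export
weighted_estimates <- function(studies, config = transfer_config()) {
  if (length(studies) == 0L) gw_stop("no study records", "gwcba_empty_input")
  rows <- lapply(studies, function(rec) {
    uv <- to_unit_value(rec, config)
    se <- impute_se(rec, uv$unit_value)
    data.frame(study_id = rec$study_id, effect = uv$unit_value, se = se,
               variance = se^2, weight = 1 / se^2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixed-effect inverse-variance weighted mean
#'
#' Pools effects Y_g with weights W_g = 1/SE_g^2, the weighting that
#' minimises the variance of the combined estimate. No heterogeneity
#' (random-effects) component is modelled.
#'
#' @param estimates a data.frame as returned by [weighted_estimates()]
#'   (columns `study_id`, `effect`, and either `weight` or `se`).
#' @return An object of class `meta_result`: `weighted_mean`, `pooled_se`
#'   (= 1/sqrt(sum W_g)), `relative_weights` (named, summing to 1) and
#'   `n_studies`.
#' @export
meta_weighted_mean <- function(estimates) {
  est <- as_estimates_df(estimates)
  w <- est$weight
  if (any(!is.finite(w)) || any(w <= 0)) {
    gw_stop("all weights must be finite and positive", "gwcba_invalid_parameter")
  }
  structure(list(
    weighted_mean = sum(w * est$effect) / sum(w),
    pooled_se = 1 / sqrt(sum(w)),
    relative_weights = stats::setNames(w / sum(w), est$study_id),
    n_studies = nrow(est)
  ), class = "meta_result")
}

as_estimates_df <- function(estimates) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0L) {
    gw_stop("`estimates` must be a non-empty data.frame", "gwcba_empty_input")
  }
  if (is.null(estimates$weight)) {
    if (is.null(estimates$se)) {
      gw_stop("`estimates` needs a `weight` or `se` column", "gwcba_invalid_parameter")
    }
    estimates$weight <- 1 / estimates$se^2
  }
  if (is.null(estimates$study_id)) {
    estimates$study_id <- as.character(seq_len(nrow(estimates)))
  }
  estimates
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d studies: weighted mean %.3f (pooled SE %.3f)\n",
              x$n_studies, x$weighted_mean, x$pooled_se))
  top <- sort(x$relative_weights, decreasing = TRUE)[1]
  cat(sprintf("  largest relative weight: %s (%.1f%%)\n",
              names(top), 100 * top))
  invisible(x)
}

#' Leave-one-out influence of each study
#'
#' For each study: its relative weight in the pooled mean and the weighted
#' mean recomputed with that study removed. Flags estimates that are driven
#' by a single dominant observation.
#'
#' @inheritParams meta_weighted_mean
#' @return A data.frame with columns `study_id`, `relative_weight`,
#'   `loo_mean`.
#' @export
influence_analysis <- function(estimates) {
  est <- as_estimates_df(estimates)
  if (nrow(est) < 2L) {
    gw_stop("influence analysis needs at least two studies", "gwcba_empty_input")
  }
  full <- meta_weighted_mean(est)
  loo <- vapply(seq_len(nrow(est)), function(i) {
    meta_weighted_mean(est[-i, , drop = FALSE])$weighted_mean
  }, numeric(1))
  data.frame(study_id = est$study_id,
             relative_weight = unname(full$relative_weights),
             loo_mean = loo, stringsAsFactors = FALSE)
}
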