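# Internal helpers shared across modules.

#' Signal a classed package error
#'
#' All user-facing validation failures raise conditions inheriting from
#' `"gwcba_error"` plus a specific subclass (e.g. `"gwcba_missing_index"`),
#' so callers can branch on the failure mode rather than on message text.
#'
#' @param msg message string.
#' @param class specific condition subclass.
#' @noRd
gw_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gwcba_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a single finite numeric value
#' @noRd
gw_check_number <- function(x, name, min = -Inf, strict = FALSE,
                            class = "gwcba_invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    gw_stop(sprintf("`%s` must be a single finite number", name), class)
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    gw_stop(sprintf("`%s` must be %s %s, got %g", name,
                    if (strict) ">" else ">=", format(min), x), class)
  }
  invisible(x)
}

#' Log a message to stderr (results stay on stdout / in files)
#' @noRd
gw_log <- function(fmt, ...) {
  message(sprintf("[greenwallcba] %s", sprintf(fmt, ...)))
}

# Display rounding used when rendering tables: monetary amounts as integers,
# ratios to 2 decimals, unit values to 2 decimals. Computation is never
# rounded; these are presentation helpers only.
round_money <- function(x) round(x, 0)
round_ratio <- function(x) round(x, 2)
round_unit <- function(x) round(x, 2)
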