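# Financial primitives: discounting, annuities, recurring-investment present
# values, consumer-price-index (CPI) updating and currency conversion.
# Every downstream valuation stage builds on these.

#' Discounting specification
#'
#' Bundles an annual discount rate, a horizon in whole years and the
#' payment-timing convention. With end-of-year ("ordinary annuity") timing the
#' factor is \eqn{(1 - (1+r)^{-T})/r}; start-of-year ("annuity-due") timing
#' multiplies that by \eqn{(1+r)}. Property annuitisation in the value-transfer
#' stage conventionally uses end-of-year timing (5\%, 50 years), while project
#' appraisal uses start-of-year timing (3\%, 40 years), because investment
#' outlays fall at the beginning of each project year.
#'
#' @param rate annual discount rate as a fraction per year; must be > 0.
#' @param horizon integer number of years; must be >= 1.
#' @param timing `"end-of-year"` (default) or `"start-of-year"`.
#' @return An object of class `discount_spec`.
#' @examples
#' annuity_factor(discount_spec(0.03, 40, "start-of-year")) # ~23.81
#' @export
discount_spec <- function(rate, horizon, timing = c("end-of-year", "start-of-year")) {
  timing <- match.arg(timing)
  gw_check_number(rate, "rate", min = 0, strict = TRUE)
  gw_check_number(horizon, "horizon", min = 1)
  if (abs(horizon - round(horizon)) > 1e-8) {
    gw_stop("`horizon` must be an integer number of years", "gwcba_invalid_parameter")
  }
  structure(list(rate = rate, horizon = as.integer(round(horizon)), timing = timing),
            class = "discount_spec")
}

#' @export
print.discount_spec <- function(x, ...) {
  cat(sprintf("<discount_spec> %.4g%%/yr over %d yr, %s timing (annuity factor %.4f)\n",
              100 * x$rate, x$horizon, x$timing, annuity_factor(x)))
  invisible(x)
}

#' Annuity factor
#'
#' The divisor that converts a present value into the equivalent constant
#' annual amount over the spec's horizon at its discount rate.
#'
#' @param spec a [discount_spec()].
#' @return A dimensionless factor.
#' @export
annuity_factor <- function(spec) {
  if (!inherits(spec, "discount_spec")) {
    gw_stop("`spec` must be a discount_spec", "gwcba_invalid_parameter")
  }
  f <- (1 - (1 + spec$rate)^(-spec$horizon)) / spec$rate
  if (spec$timing == "start-of-year") f <- f * (1 + spec$rate)
  f
}

#' Convert a present value to a constant annual amount
#'
#' @param present_value non-negative amount (any currency).
#' @param spec a [discount_spec()].
#' @return Annual amount in the same currency, per year.
#' @examples
#' # 230,000 at 5% over 50 years, end-of-year: ~12,599 per year
#' annualize(230000, discount_spec(0.05, 50))
#' @export
annualize <- function(present_value, spec) {
  gw_check_number(present_value, "present_value", min = 0)
  present_value / annuity_factor(spec)
}

#' Present value of a recurring investment
#'
#' An investment of `unit_cost` is re-incurred every `cycle` years at epochs
#' t = 0, cycle, 2*cycle, ... strictly before `horizon` (start-of-year
#' timing; end-of-year timing books each outlay one year later). No salvage
#' value or terminal correction is applied at the horizon.
#'
#' @param unit_cost cost per installation (>= 0).
#' @param cycle re-investment cycle (asset lifetime), years; must be >= 1 and
#'   <= `horizon`.
#' @param horizon project horizon, years.
#' @param rate annual discount rate, fraction.
#' @param timing payment-timing convention, as in [discount_spec()].
#' @return Present value at t = 0.
#' @examples
#' # 500 per m2 every 10 years over 40 years at 3%: PV ~ 1354.9
#' pv_recurring_investment(500, 10, 40, 0.03, "start-of-year")
#' @export
pv_recurring_investment <- function(unit_cost, cycle, horizon, rate,
                                    timing = c("start-of-year", "end-of-year")) {
  timing <- match.arg(timing)
  gw_check_number(unit_cost, "unit_cost", min = 0)
  gw_check_number(cycle, "cycle", min = 1)
  gw_check_number(horizon, "horizon", min = 1)
  gw_check_number(rate, "rate", min = 0, strict = TRUE)
  if (cycle > horizon) {
    gw_stop(sprintf("re-investment cycle (%g yr) exceeds the horizon (%g yr)",
                    cycle, horizon), "gwcba_invalid_parameter")
  }
  epochs <- cycle * (seq_len(ceiling(horizon / cycle - 1e-9)) - 1)
  if (timing == "end-of-year") epochs <- epochs + 1
  sum(unit_cost * (1 + rate)^(-epochs))
}

# ---- price index (CPI) ------------------------------------------------------

#' Consumer price index table
#'
#' @param index named numeric vector (names are years) or a data.frame with
#'   columns `year` and `index`. All index values must be > 0.
#' @return An object of class `price_index_table`.
#' @export
price_index_table <- function(index) {
  if (is.data.frame(index)) {
    stopifnot(all(c("year", "index") %in% names(index)))
    idx <- stats::setNames(as.numeric(index$index), as.character(index$year))
  } else {
    if (is.null(names(index))) {
      gw_stop("`index` must be named by year", "gwcba_invalid_parameter")
    }
    idx <- stats::setNames(as.numeric(index), names(index))
  }
  if (any(!is.finite(idx)) || any(idx <= 0)) {
    gw_stop("all price index values must be positive", "gwcba_invalid_parameter")
  }
  structure(list(index = idx), class = "price_index_table")
}

cpi_lookup <- function(table, year) {
  if (!inherits(table, "price_index_table")) {
    gw_stop("`table` must be a price_index_table", "gwcba_invalid_parameter")
  }
  v <- table$index[as.character(year)]
  if (any(is.na(v))) {
    gw_stop(sprintf("no price index for year(s): %s",
                    paste(year[is.na(v)], collapse = ", ")),
            "gwcba_missing_index")
  }
  unname(v)
}

#' Restate an amount between price years
#'
#' Multiplies by `index(to_year) / index(from_year)`.
#'
#' @param amount monetary amount.
#' @param from_year,to_year years present in `table`.
#' @param table a [price_index_table()].
#' @return Amount in `to_year` prices.
#' @examples
#' cpi <- price_index_table(c("2010" = 111.91, "2011" = 115.38))
#' cpi_adjust(2.40, 2010, 2011, cpi) # ~2.47
#' @export
cpi_adjust <- function(amount, from_year, to_year, table) {
  amount * cpi_lookup(table, to_year) / cpi_lookup(table, from_year)
}

# ---- foreign exchange -------------------------------------------------------

#' Currency conversion table
#'
#' Maps (currency code, year) to EUR per unit of the currency. EUR itself
#' always converts at 1 and need not be listed.
#'
#' @param rates data.frame with columns `currency`, `year`, `rate` (EUR per
#'   unit); all rates must be > 0.
#' @return An object of class `fx_table`.
#' @export
fx_table <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("currency", "year", "rate") %in% names(rates)))
  rates <- data.frame(currency = as.character(rates$currency),
                      year = as.integer(rates$year),
                      rate = as.numeric(rates$rate),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(rates$rate)) || any(rates$rate <= 0)) {
    gw_stop("all exchange rates must be positive", "gwcba_invalid_parameter")
  }
  structure(list(rates = rates), class = "fx_table")
}

fx_lookup <- function(table, currency, year) {
  if (identical(toupper(currency), "EUR")) return(1)
  if (!inherits(table, "fx_table")) {
    gw_stop("`table` must be an fx_table", "gwcba_invalid_parameter")
  }
  hit <- table$rates$currency == currency & table$rates$year == as.integer(year)
  if (!any(hit)) {
    gw_stop(sprintf("no EUR exchange rate for %s in %s", currency, year),
            "gwcba_missing_rate")
  }
  table$rates$rate[which(hit)[1]]
}

#' Convert a local-currency amount to EUR in a given year
#'
#' @param amount amount in `currency` units.
#' @param currency ISO currency code; `"EUR"` passes through at rate 1.
#' @param year year of the amount (nominal prices).
#' @param table an [fx_table()].
#' @return Amount in EUR of the same year.
#' @export
fx_to_eur <- function(amount, currency, year, table) {
  amount * fx_lookup(table, currency, year)
}
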