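# Benefit transfer: convert reviewed hedonic-pricing study records into
# EUR base-year per-m2 per-household-per-year amenity unit values.
#
# The chain per study g is
#   annuity  = property price / annuity factor   (rents pass through)
#   value    = premium midpoint x base           (base = annuity, or the raw
#                                                 price where the study's
#                                                 premium applies to it)
#   EUR base = value x fx(currency, year) x CPI(year -> base year)
#   Y_g      = EUR base / greenery area
# All arithmetic is kept at full floating precision; rounding happens only
# when tables are rendered.

#' Construct/validate a hedonic study record
#'
#' A record captures the raw economic facts of one published valuation
#' estimate: the property price or annual rent, its currency and data year,
#' the greenery price premium (a point value or an interval, in percent),
#' which base the premium multiplies, the greenery area the estimate refers
#' to, and what is known about its uncertainty.
#'
#' @param study_id short unique label.
#' @param data_year year of the underlying price data.
#' @param location free-text location label.
#' @param currency ISO currency code of `price`.
#' @param price_kind `"property-price"` (annuitised before use) or
#'   `"annual-rent"` (already an annual amount).
#' @param price amount in local currency; must be > 0.
#' @param premium_lo,premium_hi greenery premium bounds in percent; equal for
#'   a point estimate. The midpoint must be > 0.
#' @param premium_base `"annuity"` (default: the percentage multiplies the
#'   annualised value) or `"property-price"` (it multiplies the raw price).
#' @param greenery_area greenery area the premium refers to, m2; > 0.
#' @param uncertainty `"interval"`, `"reported-se"` or `"none"`.
#' @param rel_se relative standard error on the premium scale; required when
#'   `uncertainty == "reported-se"`.
#' @return An object of class `hedonic_study`.
#' @export
hedonic_study <- function(study_id, data_year, location = "", currency,
                          price_kind = c("property-price", "annual-rent"),
                          price, premium_lo, premium_hi = premium_lo,
                          premium_base = c("annuity", "property-price"),
                          greenery_area,
                          uncertainty = c("none", "interval", "reported-se"),
                          rel_se = NA_real_) {
  price_kind <- match.arg(price_kind)
  premium_base <- match.arg(premium_base)
  uncertainty <- match.arg(uncertainty)
  gw_check_number(price, "price", min = 0, strict = TRUE,
                  class = "gwcba_invalid_record")
  gw_check_number(greenery_area, "greenery_area", min = 0, strict = TRUE,
                  class = "gwcba_invalid_record")
  if (premium_lo > premium_hi) {
    gw_stop("premium interval must have lo <= hi", "gwcba_invalid_record")
  }
  if ((premium_lo + premium_hi) / 2 <= 0) {
    gw_stop("premium midpoint must be > 0", "gwcba_invalid_record")
  }
  if (uncertainty == "reported-se") {
    gw_check_number(rel_se, "rel_se", min = 0, strict = TRUE,
                    class = "gwcba_invalid_record")
  }
  structure(list(study_id = as.character(study_id),
                 data_year = as.integer(data_year),
                 location = as.character(location),
                 currency = as.character(currency),
                 price_kind = price_kind, price = as.numeric(price),
                 premium_lo = as.numeric(premium_lo),
                 premium_hi = as.numeric(premium_hi),
                 premium_base = premium_base,
                 greenery_area = as.numeric(greenery_area),
                 uncertainty = uncertainty, rel_se = as.numeric(rel_se)),
            class = "hedonic_study")
}

premium_midpoint <- function(record) (record$premium_lo + record$premium_hi) / 2

#' Transfer configuration
#'
#' @param fx an [fx_table()]; defaults to the packaged rates.
#' @param cpi a [price_index_table()]; defaults to the packaged EU27 CPI.
#' @param property_discount [discount_spec()] used to annuitise property
#'   prices; the conventional choice is 5\% over 50 years, end-of-year.
#' @param base_year target price year for unit values (default 2010).
#' @param household_size average persons per household (EU27 average 2.4).
#' @return An object of class `transfer_config`.
#' @export
transfer_config <- function(fx = default_fx_table(), cpi = default_cpi_table(),
                            property_discount = discount_spec(0.05, 50, "end-of-year"),
                            base_year = 2010, household_size = 2.4) {
  gw_check_number(household_size, "household_size", min = 0, strict = TRUE)
  structure(list(fx = fx, cpi = cpi, property_discount = property_discount,
                 base_year = as.integer(base_year),
                 household_size = household_size),
            class = "transfer_config")
}

#' Annualise a study's price
#'
#' Property prices are converted to the equivalent constant annual amount at
#' the configured property discounting; annual rents pass through unchanged.
#'
#' @param record a [hedonic_study()].
#' @param config a [transfer_config()].
#' @return Annual value in the record's local currency, per household per year.
#' @export
annuitize_record <- function(record, config = transfer_config()) {
  if (record$price_kind == "property-price") {
    annualize(record$price, config$property_discount)
  } else {
    record$price
  }
}

#' Annual greenery value in local currency
#'
#' The premium midpoint times its base: the annuity by default, or the raw
#' property price for studies whose percentage is stated against it.
#'
#' @inheritParams annuitize_record
#' @return Local currency per household per year.
#' @export
greenery_annual_value <- function(record, config = transfer_config()) {
  base <- if (record$premium_base == "property-price") {
    record$price
  } else {
    annuitize_record(record, config)
  }
  premium_midpoint(record) / 100 * base
}

#' Transfer one study to a base-year unit value
#'
#' @inheritParams annuitize_record
#' @return An object of class `unit_value_estimate` with fields `study_id`,
#'   `eur_base_value` (EUR/household/yr at the base year), `unit_value`
#'   (EUR/m2/household/yr), `se` (NA until imputed) and `area` (m2).
#' @export
to_unit_value <- function(record, config = transfer_config()) {
  gav <- greenery_annual_value(record, config)
  eur <- fx_to_eur(gav, record$currency, record$data_year, config$fx)
  eur_base <- cpi_adjust(eur, record$data_year, config$base_year, config$cpi)
  structure(list(study_id = record$study_id,
                 eur_base_value = eur_base,
                 unit_value = eur_base / record$greenery_area,
                 se = NA_real_,
                 area = record$greenery_area),
            class = "unit_value_estimate")
}

#' Convert a per-household value to per person
#'
#' @param value EUR per household per year.
#' @param config a [transfer_config()] (supplies the household size).
#' @return EUR per person per year.
#' @export
per_person <- function(value, config = transfer_config()) {
  value / config$household_size
}

#' Arithmetic mean of unit values
#'
#' @param estimates a list of `unit_value_estimate` objects or a numeric
#'   vector of unit values.
#' @param exclude_max drop the single largest value before averaging
#'   (robustness check against a dominant outlier).
#' @return Mean unit value, EUR/m2/household/yr.
#' @export
summarize_unit_values <- function(estimates, exclude_max = FALSE) {
  values <- if (is.numeric(estimates)) estimates else
    vapply(estimates, function(e) e$unit_value, numeric(1))
  if (length(values) == 0L) {
    gw_stop("no unit values to summarise", "gwcba_empty_input")
  }
  if (exclude_max && length(values) > 1L) {
    values <- values[-which.max(values)]
  }
  mean(values)
}

#' Empirical central interval of unit values
#'
#' Central `level` interval of the study unit values, computed as empirical
#' quantiles. With only a handful of studies this is approximate and reported
#' as descriptive context, never used in pooling.
#'
#' @inheritParams summarize_unit_values
#' @param level central probability mass (default 0.90).
#' @return Length-2 numeric vector (lower, upper).
#' @export
unit_value_interval <- function(estimates, level = 0.90) {
  values <- if (is.numeric(estimates)) estimates else
    vapply(estimates, function(e) e$unit_value, numeric(1))
  if (length(values) == 0L) gw_stop("no unit values", "gwcba_empty_input")
  a <- (1 - level) / 2
  unname(stats::quantile(values, c(a, 1 - a)))
}

#' Transfer a whole study collection
#'
#' Applies [to_unit_value()] to every record and assembles a table mirroring
#' the review-table layout: annuity, greenery value, base-year EUR value and
#' per-m2 unit value per study.
#'
#' @param studies list of [hedonic_study()] records (e.g. from
#'   [read_studies()] or [load_fixture()]).
#' @param config a [transfer_config()].
#' @return A data.frame with one row per study.
#' @export
transfer_table <- function(studies, config = transfer_config()) {
  if (length(studies) == 0L) gw_stop("no study records", "gwcba_empty_input")
  rows <- lapply(studies, function(rec) {
    uv <- to_unit_value(rec, config)
    data.frame(
      study_id = rec$study_id,
      data_year = rec$data_year,
      location = rec$location,
      currency = rec$currency,
      price = rec$price,
      annuity = annuitize_record(rec, config),
      premium_pct = premium_midpoint(rec),
      greenery_value = greenery_annual_value(rec, config),
      fx_rate = fx_lookup(config$fx, rec$currency, rec$data_year),
      cpi_factor = cpi_lookup(config$cpi, config$base_year) /
        cpi_lookup(config$cpi, rec$data_year),
      eur_base_value = uv$eur_base_value,
      greenery_area = rec$greenery_area,
      unit_value = uv$unit_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
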