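# Monetisation of noise-level reductions, with a lower cut-off below which
# reductions carry no economic value, an upper validity cap on the unit
# price, and a conversion factor for improvements on the quiet side of a
# building (a 3 dB quiet-side reduction counts as 1 dB on the most exposed
# facade at the default factor of 0.3).

#' Noise valuation parameters
#'
#' @param unit_price EUR per person per dB(A) per year, in `price_year`
#'   prices. The default 10.095 (2002) is the standard European annoyance
#'   valuation, valid for levels below the cap.
#' @param price_year price year of `unit_price`.
#' @param validity_cap dB(A) level above which no additional value accrues
#'   (default 71).
#' @param cutoff dB(A) level below which reductions are worthless
#'   (default 45).
#' @param quiet_side_factor fraction in (0, 1] converting quiet-side decibel
#'   reductions to their most-exposed-facade equivalent (default 0.3).
#' @return An object of class `noise_valuation_params`.
#' @export
noise_valuation_params <- function(unit_price = 10.095, price_year = 2002,
                                   validity_cap = 71, cutoff = 45,
                                   quiet_side_factor = 0.3) {
  gw_check_number(unit_price, "unit_price", min = 0)
  gw_check_number(quiet_side_factor, "quiet_side_factor", min = 0, strict = TRUE)
  if (quiet_side_factor > 1) {
    gw_stop("`quiet_side_factor` must be in (0, 1]", "gwcba_invalid_parameter")
  }
  if (cutoff >= validity_cap) {
    gw_stop("`cutoff` must be below `validity_cap`", "gwcba_invalid_parameter")
  }
  structure(list(unit_price = unit_price, price_year = as.integer(price_year),
                 validity_cap = validity_cap, cutoff = cutoff,
                 quiet_side_factor = quiet_side_factor),
            class = "noise_valuation_params")
}

#' Facade exposure record
#'
#' Sound levels before/after a measure on one facade group and the number of
#' affected persons (may be fractional: apartments times household size).
#'
#' @param level_before,level_after dB(A) levels; `level_after <= level_before`
#'   for a benefit.
#' @param side `"quiet"` or `"most-exposed"`.
#' @param persons affected person count, >= 0.
#' @return An object of class `facade_exposure`.
#' @export
facade_exposure <- function(level_before, level_after,
                            side = c("quiet", "most-exposed"), persons) {
  side <- match.arg(side)
  gw_check_number(persons, "persons", min = 0)
  structure(list(level_before = level_before, level_after = level_after,
                 side = side, persons = persons),
            class = "facade_exposure")
}

#' Economically valued decibel reduction
#'
#' Clamps the exposure change to the valuation band \[cutoff, validity_cap\]
#' (levels above the cap earn nothing extra; improvements below the cut-off
#' earn nothing) and converts quiet-side reductions by the quiet-side factor.
#'
#' @param exposure a [facade_exposure()].
#' @param params a [noise_valuation_params()].
#' @return Equivalent dB on the most-exposed-facade scale.
#' @examples
#' p <- noise_valuation_params()
#' valued_reduction(facade_exposure(56.3, 51.8, "quiet", 115), p) # 4.5 * 0.3
#' @export
valued_reduction <- function(exposure, params = noise_valuation_params()) {
  raw <- max(0, min(exposure$level_before, params$validity_cap) -
                  max(exposure$level_after, params$cutoff))
  if (exposure$side == "quiet") raw * params$quiet_side_factor else raw
}

#' Annual monetised noise benefit over a set of exposures
#'
#' Sums persons x valued reduction x the CPI-updated unit price across
#' exposure groups.
#'
#' @param exposures list of [facade_exposure()] records.
#' @param params a [noise_valuation_params()].
#' @param project_year year whose prices the benefit is stated in.
#' @param cpi a [price_index_table()] covering `price_year` and
#'   `project_year`.
#' @return EUR per year.
#' @export
annual_noise_benefit <- function(exposures, params = noise_valuation_params(),
                                 project_year, cpi = default_cpi_table()) {
  if (inherits(exposures, "facade_exposure")) exposures <- list(exposures)
  price <- cpi_adjust(params$unit_price, params$price_year, project_year, cpi)
  sum(vapply(exposures, function(e) {
    e$persons * valued_reduction(e, params) * price
  }, numeric(1)))
}

#' Per-person annual value of a decibel improvement (unadjusted)
#'
#' Reporting convenience: the CPI-updated unit price times a nominal decibel
#' change, with no quiet-side conversion or cut-off applied.
#'
#' @param delta_db nominal reduction in dB(A), >= 0.
#' @inheritParams annual_noise_benefit
#' @return EUR per person per year.
#' @export
per_person_unadjusted_benefit <- function(delta_db,
                                          params = noise_valuation_params(),
                                          project_year,
                                          cpi = default_cpi_table()) {
  gw_check_number(delta_db, "delta_db", min = 0)
  delta_db * cpi_adjust(params$unit_price, params$price_year, project_year, cpi)
}
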