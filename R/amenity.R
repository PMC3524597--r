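# Monetisation of the non-acoustic amenity/aesthetic benefit of a green
# wall: a per-m2 per-person unit value (from the pooled hedonic evidence)
# applied to a beneficiary roster. Amenity and noise benefits are summed at
# the CBA layer with no interaction, on the assumption that the hedonic
# amenity values exclude noise effects.

#' Amenity valuation parameters
#'
#' @param unit_value EUR per m2 of green wall per person per year, stated in
#'   `value_year` prices; >= 0.
#' @param value_year price year of the unit value (default 2010).
#' @return An object of class `amenity_params`.
#' @export
amenity_params <- function(unit_value, value_year = 2010) {
  gw_check_number(unit_value, "unit_value", min = 0)
  structure(list(unit_value = unit_value, value_year = as.integer(value_year)),
            class = "amenity_params")
}

#' Beneficiary roster
#'
#' Person counts for the amenity benefit: residents of the treated building
#' and external persons with a direct view of the wall. Counts may be
#' fractional (apartments times average household size).
#'
#' @param resident_persons,external_persons person counts, >= 0.
#' @return An object of class `beneficiary_roster`.
#' @export
beneficiary_roster <- function(resident_persons, external_persons = 0) {
  gw_check_number(resident_persons, "resident_persons", min = 0)
  gw_check_number(external_persons, "external_persons", min = 0)
  structure(list(resident_persons = resident_persons,
                 external_persons = external_persons),
            class = "beneficiary_roster")
}

total_persons <- function(roster) roster$resident_persons + roster$external_persons

#' Annual monetised amenity benefit
#'
#' area x CPI-updated unit value x total beneficiary persons. Bilinear in
#' area and persons; splitting the roster and summing group benefits equals
#' the pooled computation exactly.
#'
#' @param area green wall area, m2, >= 0.
#' @param roster a [beneficiary_roster()].
#' @param params an [amenity_params()].
#' @param project_year year whose prices the benefit is stated in.
#' @param cpi a [price_index_table()].
#' @return EUR per year.
#' @export
annual_amenity_benefit <- function(area, roster, params, project_year,
                                   cpi = default_cpi_table()) {
  gw_check_number(area, "area", min = 0)
  price <- cpi_adjust(params$unit_value, params$value_year, project_year, cpi)
  area * price * total_persons(roster)
}
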