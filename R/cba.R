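# Scenario cost-benefit analysis: annualised incremental costs (recurring
# investment plus yearly maintenance) against annual noise and amenity
# benefits, summarised as a benefit-cost ratio.

SCENARIO_SCHEMA <- "greenwallcba/scenario/v1"

#' Green wall scenario
#'
#' One demonstration project: wall geometry, incremental unit costs (relative
#' to a wall without greenery), project discounting, the facade exposures the
#' wall improves, the amenity beneficiary roster, and the valuation
#' parameters for both benefit streams.
#'
#' @param name scenario label.
#' @param area green wall area, m2, > 0.
#' @param invest_unit_cost installation cost, EUR/m2 (incremental).
#' @param invest_lifetime wall lifetime, years; re-investment cycle.
#' @param maintenance_unit_cost yearly maintenance, EUR/m2/yr.
#' @param cost_year price year of the unit costs.
#' @param project_discount [discount_spec()] for the project appraisal
#'   (default 3\%, 40 years, start-of-year).
#' @param project_year year whose prices all annual flows are stated in.
#' @param exposures list of [facade_exposure()] records.
#' @param roster a [beneficiary_roster()] for the amenity benefit.
#' @param noise_params a [noise_valuation_params()].
#' @param amenity_params an [amenity_params()].
#' @return An object of class `green_wall_scenario`.
#' @export
green_wall_scenario <- function(name, area, invest_unit_cost = 500,
                                invest_lifetime = 10,
                                maintenance_unit_cost = 25, cost_year = 2011,
                                project_discount = discount_spec(0.03, 40, "start-of-year"),
                                project_year = 2011, exposures = list(),
                                roster = beneficiary_roster(0, 0),
                                noise_params = noise_valuation_params(),
                                amenity_params = amenity_params(2.4, 2010)) {
  gw_check_number(area, "area", min = 0, strict = TRUE)
  gw_check_number(invest_unit_cost, "invest_unit_cost", min = 0)
  gw_check_number(maintenance_unit_cost, "maintenance_unit_cost", min = 0)
  if (inherits(exposures, "facade_exposure")) exposures <- list(exposures)
  structure(list(name = as.character(name), area = area,
                 invest_unit_cost = invest_unit_cost,
                 invest_lifetime = invest_lifetime,
                 maintenance_unit_cost = maintenance_unit_cost,
                 cost_year = as.integer(cost_year),
                 project_discount = project_discount,
                 project_year = as.integer(project_year),
                 exposures = exposures, roster = roster,
                 noise_params = noise_params,
                 amenity_params = amenity_params),
            class = "green_wall_scenario")
}

#' Annualised scenario costs
#'
#' Investment: the present value of the recurring installation cost over the
#' project horizon, annualised by the project annuity factor and scaled by
#' area. Maintenance: area times the yearly unit cost.
#'
#' @param scenario a [green_wall_scenario()].
#' @return Named list `annual_investment`, `annual_maintenance` (EUR/yr).
#' @export
annual_costs <- function(scenario) {
  pv <- pv_recurring_investment(scenario$invest_unit_cost,
                                scenario$invest_lifetime,
                                scenario$project_discount$horizon,
                                scenario$project_discount$rate,
                                scenario$project_discount$timing)
  list(annual_investment = scenario$area * annualize(pv, scenario$project_discount),
       annual_maintenance = scenario$area * scenario$maintenance_unit_cost)
}

#' Run the cost-benefit analysis for a scenario
#'
#' @param scenario a [green_wall_scenario()].
#' @param cpi a [price_index_table()] covering all price years involved.
#' @return An object of class `cba_result` with annual line items
#'   (`annual_investment`, `annual_maintenance`, `noise_benefit`,
#'   `amenity_benefit`), the totals, and `bc_ratio` computed at full
#'   precision.
#' @export
run_cba <- function(scenario, cpi = default_cpi_table()) {
  costs <- annual_costs(scenario)
  noise <- annual_noise_benefit(scenario$exposures, scenario$noise_params,
                                scenario$project_year, cpi)
  amenity <- annual_amenity_benefit(scenario$area, scenario$roster,
                                    scenario$amenity_params,
                                    scenario$project_year, cpi)
  total_costs <- costs$annual_investment + costs$annual_maintenance
  total_benefits <- noise + amenity
  if (total_costs <= 0) {
    gw_stop("total annual costs are zero: benefit-cost ratio undefined",
            "gwcba_undefined_ratio")
  }
  structure(list(scenario = scenario$name,
                 annual_investment = costs$annual_investment,
                 annual_maintenance = costs$annual_maintenance,
                 noise_benefit = noise, amenity_benefit = amenity,
                 total_benefits = total_benefits, total_costs = total_costs,
                 bc_ratio = total_benefits / total_costs),
            class = "cba_result")
}

#' @export
print.cba_result <- function(x, ...) {
  cat(sprintf("<cba_result> %s\n", x$scenario))
  line <- function(label, benefit = NA, cost = NA) {
    cat(sprintf("  %-28s %10s %10s\n", label,
                ifelse(is.na(benefit), "", format(round_money(benefit), big.mark = ",")),
                ifelse(is.na(cost), "", format(round_money(cost), big.mark = ","))))
  }
  cat(sprintf("  %-28s %10s %10s\n", "", "Benefits", "Costs"))
  line("Investment costs", cost = x$annual_investment)
  line("Maintenance costs", cost = x$annual_maintenance)
  line("Noise attenuation benefits", benefit = x$noise_benefit)
  line("Amenity/aesthetic benefits", benefit = x$amenity_benefit)
  line("Total", benefit = x$total_benefits, cost = x$total_costs)
  cat(sprintf("  B/C ratio: %.2f (full precision %.6f)\n",
              round_ratio(x$bc_ratio), x$bc_ratio))
  invisible(x)
}

#' Ratio of amenity to noise benefits
#'
#' @param result a `cba_result`.
#' @return amenity_benefit / noise_benefit.
#' @export
benefit_share <- function(result) {
  if (result$noise_benefit <= 0) {
    gw_stop("noise benefit is zero: share undefined", "gwcba_undefined_ratio")
  }
  result$amenity_benefit / result$noise_benefit
}

# ---- scenario serialisation -------------------------------------------------

#' Read a scenario from a YAML file
#'
#' Scenario files are versioned (`schema: greenwallcba/scenario/v1`) with
#' blocks `costs`, `discounting`, `exposures`, `noise_valuation` and
#' `amenity` (the latter holding the beneficiary `roster`), plus an optional
#' `mc` block read by [mc_spec_from_scenario_file()].
#'
#' @param path path to the scenario YAML.
#' @return A [green_wall_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    gw_stop(sprintf("scenario file not found: %s", path), "gwcba_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, SCENARIO_SCHEMA)) {
    gw_stop(sprintf("unsupported scenario schema: %s", raw$schema %||% "<missing>"),
            "gwcba_io_error")
  }
  d <- raw$discounting
  np <- raw$noise_valuation %||% list()
  am <- raw$amenity
  exposures <- lapply(raw$exposures, function(e) {
    facade_exposure(e$level_before, e$level_after, e$side, e$persons)
  })
  green_wall_scenario(
    name = raw$name, area = raw$area_m2,
    invest_unit_cost = raw$costs$invest_unit_cost,
    invest_lifetime = raw$costs$invest_lifetime,
    maintenance_unit_cost = raw$costs$maintenance_unit_cost,
    cost_year = raw$costs$cost_year %||% raw$project_year,
    project_discount = discount_spec(d$rate, d$horizon, d$timing),
    project_year = raw$project_year,
    exposures = exposures,
    roster = beneficiary_roster(am$roster$resident_persons,
                                am$roster$external_persons %||% 0),
    noise_params = noise_valuation_params(
      unit_price = np$unit_price %||% 10.095,
      price_year = np$price_year %||% 2002,
      validity_cap = np$validity_cap %||% 71,
      cutoff = np$cutoff %||% 45,
      quiet_side_factor = np$quiet_side_factor %||% 0.3),
    amenity_params = amenity_params(am$unit_value, am$value_year %||% 2010)
  )
}

#' Write a scenario to a YAML file
#'
#' Inverse of [read_scenario()]; round-trips losslessly.
#'
#' @param scenario a [green_wall_scenario()].
#' @param path output path.
#' @param mc optional [mc_spec()] to embed as the `mc` block.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path, mc = NULL) {
  s <- scenario
  raw <- list(
    schema = SCENARIO_SCHEMA,
    name = s$name,
    area_m2 = s$area,
    project_year = s$project_year,
    costs = list(invest_unit_cost = s$invest_unit_cost,
                 invest_lifetime = s$invest_lifetime,
                 maintenance_unit_cost = s$maintenance_unit_cost,
                 cost_year = s$cost_year),
    discounting = list(rate = s$project_discount$rate,
                       horizon = s$project_discount$horizon,
                       timing = s$project_discount$timing),
    exposures = lapply(s$exposures, function(e) {
      list(side = e$side, level_before = e$level_before,
           level_after = e$level_after, persons = e$persons)
    }),
    noise_valuation = unclass(s$noise_params),
    amenity = list(unit_value = s$amenity_params$unit_value,
                   value_year = s$amenity_params$value_year,
                   roster = list(resident_persons = s$roster$resident_persons,
                                 external_persons = s$roster$external_persons))
  )
  if (!is.null(mc)) {
    raw$mc <- list(draws = mc$draws,
                   perturbations = as.list(mc$perturbations),
                   lower_truncation = mc$lower_truncation, band = mc$band)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}
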