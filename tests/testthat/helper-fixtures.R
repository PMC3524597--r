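# Shared helpers for the test-suite. Fixtures are built from the packaged
# plain-text files; nothing is downloaded or cached.

default_config <- function() transfer_config()

# relative-difference expectation for comparing computed values against
# published (display-rounded) reference numbers
expect_rel <- function(actual, reference, tol) {
  expect_lt(abs(actual - reference) / abs(reference), tol)
}

# a minimal scenario used by property tests (values are arbitrary but valid)
toy_scenario <- function(amenity_unit = 1.5, db = 3, persons = 50,
                         area = 100) {
  green_wall_scenario(
    name = "toy", area = area,
    invest_unit_cost = 300, invest_lifetime = 10,
    maintenance_unit_cost = 20, cost_year = 2011,
    project_discount = discount_spec(0.03, 40, "start-of-year"),
    project_year = 2011,
    exposures = list(facade_exposure(60, 60 - db, "quiet", persons)),
    roster = beneficiary_roster(persons, 5),
    noise_params = noise_valuation_params(),
    amenity_params = amenity_params(amenity_unit, 2010)
  )
}
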