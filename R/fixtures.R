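# Packaged worked-example fixtures: the reviewed hedonic study collection
# (with its uncertainty metadata and the published reference values) and the
# four demonstration green-wall scenarios.

FIXTURE_NAMES <- c("table1", "table2", "demo_3m", "demo_19m",
                   "demo_3m_low", "demo_19m_low")

#' Load a packaged fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{`table1`}{the eight reviewed hedonic study records (list of
#'     [hedonic_study()]); their transfer reproduces the published annuities,
#'     greenery values and per-m2 unit values.}
#'   \item{`table2`}{the same records plus the published unit values and
#'     inverse-variance weights as a reference data.frame (`$studies`,
#'     `$printed`).}
#'   \item{`demo_3m`, `demo_19m`}{the 3 m / 19.2 m facade-opening
#'     demonstration scenarios with the high (pooled-mean-excluding-outlier)
#'     amenity unit value.}
#'   \item{`demo_3m_low`, `demo_19m_low`}{the same walls with the low
#'     (outlier-dominated) amenity unit value.}
#' }
#'
#' @param name fixture name.
#' @return See above; scenarios are [green_wall_scenario()] objects.
#' @export
load_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES) {
    gw_stop(sprintf("unknown fixture '%s' (available: %s)", name,
                    paste(FIXTURE_NAMES, collapse = ", ")), "gwcba_io_error")
  }
  extdata <- function(f) system.file("extdata", f, package = "greenwallcba")
  switch(name,
    "table1" = read_studies(extdata("studies_table1.csv")),
    "table2" = list(
      studies = read_studies(extdata("studies_table1.csv")),
      printed = utils::read.csv(extdata("table2_printed.csv"),
                                stringsAsFactors = FALSE)
    ),
    read_scenario(extdata(paste0("scenario_", name, ".yaml")))
  )
}

#' Published reference values for the packaged study table
#'
#' The printed annuity, greenery value, base-year EUR value and unit value
#' per study, used by the test-suite to verify the transfer chain.
#'
#' @return A data.frame keyed by `study_id`.
#' @export
table1_printed <- function() {
  utils::read.csv(system.file("extdata", "table1_printed.csv",
                              package = "greenwallcba"),
                  stringsAsFactors = FALSE)
}
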