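# Packaged parameter tables (CPI, exchange rates, transfer defaults) and the
# loader for user-supplied parameter files.

.gw_cache <- new.env(parent = emptyenv())

#' Read a parameter file
#'
#' Parameter files are YAML (or JSON) with a `schema` tag, a `cpi` block
#' mapping year to index value, an `fx` list of `{currency, year, rate}`
#' entries, and transfer defaults (`base_year`, `household_size`,
#' `property_discount`).
#'
#' @param path path to the YAML/JSON parameter file.
#' @return A list with elements `cpi` ([price_index_table()]),
#'   `fx` ([fx_table()]), `base_year`, `household_size`, `property_discount`
#'   ([discount_spec()]) and `schema`.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    gw_stop(sprintf("parameter file not found: %s", path), "gwcba_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("cpi", "fx")) {
    if (is.null(raw[[field]])) {
      gw_stop(sprintf("parameter file lacks required block `%s`", field),
              "gwcba_io_error")
    }
  }
  fx_df <- if (is.data.frame(raw$fx)) raw$fx else
    do.call(rbind, lapply(raw$fx, function(e) {
      data.frame(currency = e$currency, year = e$year, rate = e$rate,
                 stringsAsFactors = FALSE)
    }))
  pd <- raw$property_discount %||% list(rate = 0.05, horizon = 50, timing = "end-of-year")
  list(
    schema = raw$schema %||% "greenwallcba/parameters/v1",
    cpi = price_index_table(unlist(raw$cpi)),
    fx = fx_table(fx_df),
    base_year = as.integer(raw$base_year %||% 2010),
    household_size = as.numeric(raw$household_size %||% 2.4),
    property_discount = discount_spec(pd$rate, pd$horizon, pd$timing)
  )
}

#' Packaged default parameters
#'
#' The parameter tables shipped with the package: EU27 CPI values (93.58 for
#' 2002, 111.91 for 2010, 115.38 for 2011, with earlier years back-derived
#' from the published update factors) and the study-year exchange rates used
#' by the packaged hedonic-study records.
#'
#' @return See [read_parameters()].
#' @export
default_parameters <- function() {
  if (is.null(.gw_cache$params)) {
    path <- system.file("extdata", "parameters.yaml", package = "greenwallcba")
    .gw_cache$params <- read_parameters(path)
  }
  .gw_cache$params
}

#' @rdname default_parameters
#' @export
default_cpi_table <- function() default_parameters()$cpi

#' @rdname default_parameters
#' @export
default_fx_table <- function() default_parameters()$fx
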