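# Readers/writers and the end-to-end pipeline driver. Data files are
# comma-separated UTF-8 with dot decimal separators; display formatting
# (thousands separators, rounding) never appears in data files. Logging goes
# to stderr; results go to files, keeping stdout clean for piping.

STUDY_COLUMNS <- c("study_id", "data_year", "currency", "price_kind",
                   "premium_lo", "premium_hi", "premium_base",
                   "greenery_area", "uncertainty")

#' Read hedonic study records from CSV
#'
#' Required columns: `study_id`, `data_year`, `currency`, `price_kind`,
#' `premium_lo`, `premium_hi`, `premium_base`, `greenery_area`,
#' `uncertainty`; plus `price` and optionally `price_ref` (the id of another
#' row whose price this record borrows — used where a review study supplies
#' only a premium and the base price is taken from an earlier record),
#' `location` and `rel_se`. Every row is validated through
#' [hedonic_study()]; failures report the offending row.
#'
#' @param path CSV path.
#' @return A list of [hedonic_study()] records.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) {
    gw_stop(sprintf("study file not found: %s", path), "gwcba_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    gw_stop(sprintf("study file is empty: %s", path), "gwcba_empty_input")
  }
  missing <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing) > 0) {
    gw_stop(sprintf("study file lacks column(s): %s",
                    paste(missing, collapse = ", ")), "gwcba_io_error")
  }
  if (is.null(df$price_ref)) df$price_ref <- NA_character_
  if (is.null(df$rel_se)) df$rel_se <- NA_real_
  if (is.null(df$location)) df$location <- ""
  # resolve shared-price references before validation
  for (i in seq_len(nrow(df))) {
    ref <- df$price_ref[i]
    if (!is.na(ref) && nzchar(ref)) {
      j <- match(ref, df$study_id)
      if (is.na(j)) {
        gw_stop(sprintf("row %d (%s): price_ref '%s' matches no study_id",
                        i, df$study_id[i], ref), "gwcba_io_error")
      }
      df$price[i] <- df$price[j]
    }
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    records[[i]] <- tryCatch(
      hedonic_study(study_id = df$study_id[i], data_year = df$data_year[i],
                    location = df$location[i], currency = df$currency[i],
                    price_kind = df$price_kind[i], price = df$price[i],
                    premium_lo = df$premium_lo[i],
                    premium_hi = df$premium_hi[i],
                    premium_base = df$premium_base[i],
                    greenery_area = df$greenery_area[i],
                    uncertainty = df$uncertainty[i], rel_se = df$rel_se[i]),
      gwcba_error = function(e) {
        gw_stop(sprintf("row %d (%s): %s", i, df$study_id[i], conditionMessage(e)),
                "gwcba_invalid_record")
      })
  }
  records
}

#' Write study records to CSV
#'
#' @param studies list of [hedonic_study()] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  df <- do.call(rbind, lapply(studies, function(r) {
    data.frame(study_id = r$study_id, data_year = r$data_year,
               location = r$location, currency = r$currency,
               price_kind = r$price_kind, price = r$price,
               price_ref = NA_character_, premium_lo = r$premium_lo,
               premium_hi = r$premium_hi, premium_base = r$premium_base,
               greenery_area = r$greenery_area, uncertainty = r$uncertainty,
               rel_se = r$rel_se, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Render a CBA result as a display table
#'
#' Mirrors the published table layout, with monetary amounts rounded to
#' integers and the benefit-cost ratio to two decimals. The unrounded ratio
#' is kept alongside, since a ratio recomputed from rounded line items can
#' differ in the last digit.
#'
#' @param result a `cba_result`.
#' @return A data.frame with columns `item`, `benefits`, `costs`,
#'   `bc_ratio`.
#' @export
cba_table <- function(result) {
  data.frame(
    item = c("Investment costs", "Maintenance costs",
             "Noise attenuation benefits", "Amenity/aesthetic benefits",
             "Total"),
    benefits = c(NA, NA, round_money(result$noise_benefit),
                 round_money(result$amenity_benefit),
                 round_money(result$total_benefits)),
    costs = c(round_money(result$annual_investment),
              round_money(result$annual_maintenance), NA, NA,
              round_money(result$total_costs)),
    bc_ratio = c(NA, NA, NA, NA, round_ratio(result$bc_ratio)),
    stringsAsFactors = FALSE
  )
}

#' Write pipeline results to disk
#'
#' Writes a machine-readable JSON file (full precision, with schema tag and
#' seed) and, for tabular results, a display-rounded CSV next to it.
#'
#' @param results a named list of result objects (`cba_result`,
#'   `meta_result`, `mc_result`, data.frames, or plain lists).
#' @param dir output directory (created if needed).
#' @param name base file name (without extension).
#' @param seed the seed used to produce the results (recorded in the JSON).
#' @param format `"json"`, `"csv"` or `"both"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(results, dir, name, seed = NA_integer_,
                         format = c("both", "json", "csv")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  strip <- function(x) {
    if (inherits(x, "mc_result")) {
      x <- unclass(x)
      x$bc_samples <- NULL  # summaries only; samples are regenerable from the seed
    }
    if (is.object(x) && !is.data.frame(x)) x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) {
      x <- lapply(x, function(el) if (is.object(el) && !is.data.frame(el))
        strip(el) else el)
    }
    x
  }
  if (format %in% c("both", "json")) {
    payload <- list(schema = "greenwallcba/report/v1",
                    package_version = as.character(utils::packageVersion("greenwallcba")),
                    seed = seed, results = lapply(results, strip))
    json_path <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
    written <- c(written, json_path)
  }
  if (format %in% c("both", "csv")) {
    for (nm in names(results)) {
      x <- results[[nm]]
      tab <- if (inherits(x, "cba_result")) cba_table(x) else
        if (is.data.frame(x)) x else NULL
      if (!is.null(tab)) {
        csv_path <- file.path(dir, paste0(name, "_", nm, ".csv"))
        utils::write.csv(tab, csv_path, row.names = FALSE, na = "")
        written <- c(written, csv_path)
      }
    }
  }
  gw_log("wrote %s", paste(written, collapse = ", "))
  invisible(written)
}

#' Run the full pipeline
#'
#' Value transfer -> pooling -> per-scenario CBA -> Monte Carlo, writing one
#' report per stage into `out_dir`. All stages are driven by packaged
#' defaults unless paths are supplied.
#'
#' @param out_dir output directory.
#' @param studies_path CSV of study records (default: packaged review table).
#' @param scenario_paths character vector of scenario YAML paths (default:
#'   the four packaged demonstration scenarios).
#' @param parameters_path parameter YAML (default: packaged tables).
#' @param seed global RNG seed for the Monte Carlo stage.
#' @param mc_draws draws per scenario (default 10,000); set to 0 to skip the
#'   Monte Carlo stage.
#' @return A list with elements `transfer`, `meta`, `cba`, `mc` (the
#'   in-memory results), invisibly.
#' @export
run_pipeline <- function(out_dir, studies_path = NULL, scenario_paths = NULL,
                         parameters_path = NULL, seed = 1L, mc_draws = 10000) {
  params <- if (is.null(parameters_path)) default_parameters() else
    read_parameters(parameters_path)
  config <- transfer_config(fx = params$fx, cpi = params$cpi,
                            property_discount = params$property_discount,
                            base_year = params$base_year,
                            household_size = params$household_size)
  studies <- if (is.null(studies_path)) load_fixture("table1") else
    read_studies(studies_path)
  if (is.null(scenario_paths)) {
    scenario_paths <- vapply(c("demo_3m", "demo_19m", "demo_3m_low", "demo_19m_low"),
                             function(n) system.file("extdata",
                                                     paste0("scenario_", n, ".yaml"),
                                                     package = "greenwallcba"),
                             character(1))
  }
  gw_log("transfer: %d study records", length(studies))
  transfer <- transfer_table(studies, config)
  estimates <- weighted_estimates(studies, config)
  meta <- meta_weighted_mean(estimates)
  infl <- influence_analysis(estimates)
  write_report(list(table = transfer,
                    mean_unit_value = summarize_unit_values(transfer$unit_value),
                    mean_excl_max = summarize_unit_values(transfer$unit_value,
                                                          exclude_max = TRUE)),
               out_dir, "transfer", seed)
  write_report(list(estimates = estimates, pooled = meta, influence = infl),
               out_dir, "meta", seed)
  cba <- list()
  mc <- list()
  for (path in scenario_paths) {
    scenario <- read_scenario(path)
    gw_log("cba: scenario %s", scenario$name)
    cba[[scenario$name]] <- run_cba(scenario, params$cpi)
    if (mc_draws > 0) {
      spec <- mc_spec_from_scenario_file(path)
      spec$draws <- as.integer(mc_draws)
      mc[[scenario$name]] <- simulate_bc(scenario, spec, seed = seed,
                                         cpi = params$cpi)
    }
  }
  write_report(cba, out_dir, "cba", seed)
  if (length(mc) > 0) write_report(mc, out_dir, "mc", seed)
  invisible(list(transfer = transfer, meta = meta, influence = infl,
                 cba = cba, mc = mc))
}
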