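# Monte Carlo sensitivity analysis of the benefit-cost ratio. Named scenario
# inputs are perturbed multiplicatively with truncated-normal draws centred
# on the point estimate, SD equal to the stated fractional uncertainty times
# the estimate, truncated below so no draw is negative or essentially zero.

MC_INPUTS <- c("amenity_unit_value", "noise_db", "invest_unit_cost",
               "maintenance_unit_cost", "persons")

#' Monte Carlo specification
#'
#' @param draws number of simulations (default 10,000).
#' @param perturbations named fractional uncertainties. Recognised names:
#'   `amenity_unit_value` (default 0.50), `noise_db`, `invest_unit_cost`,
#'   `maintenance_unit_cost` (default 0.30 each) and `persons` (default
#'   0.15, applied to every beneficiary count). A fraction of 0 freezes that
#'   input.
#' @param lower_truncation minimum admissible multiple of each point estimate
#'   (default 0.01): draws below it are rejected and redrawn, guaranteeing
#'   strictly positive inputs.
#' @param band central probability mass of the reported quantile band
#'   (default 0.90).
#' @return An object of class `mc_spec`.
#' @export
mc_spec <- function(draws = 10000,
                    perturbations = c(amenity_unit_value = 0.50,
                                      noise_db = 0.30,
                                      invest_unit_cost = 0.30,
                                      maintenance_unit_cost = 0.30,
                                      persons = 0.15),
                    lower_truncation = 0.01, band = 0.90) {
  gw_check_number(draws, "draws", min = 1)
  gw_check_number(band, "band", min = 0, strict = TRUE)
  if (band >= 1) gw_stop("`band` must be in (0, 1)", "gwcba_invalid_parameter")
  perturbations <- unlist(perturbations)
  unknown <- setdiff(names(perturbations), MC_INPUTS)
  if (length(unknown) > 0) {
    gw_stop(sprintf("unknown perturbation input(s): %s",
                    paste(unknown, collapse = ", ")), "gwcba_invalid_parameter")
  }
  if (any(perturbations < 0)) {
    gw_stop("fractional uncertainties must be >= 0", "gwcba_invalid_parameter")
  }
  full <- stats::setNames(numeric(length(MC_INPUTS)), MC_INPUTS)
  if (length(perturbations) > 0) full[names(perturbations)] <- perturbations
  structure(list(draws = as.integer(draws), perturbations = full,
                 lower_truncation = lower_truncation, band = band),
            class = "mc_spec")
}

#' Lower-truncated normal multiplier draws
#'
#' Rejection sampling from Normal(1, frac^2) truncated below at `lower`;
#' acceptance is ~99.9% at the default parameters, and the sequence is fully
#' determined by the RNG state.
#'
#' @param n number of draws.
#' @param frac fractional SD; 0 returns a vector of 1s.
#' @param lower lower truncation bound on the multiplier scale.
#' @return Numeric vector of n multipliers, all > `lower`.
#' @export
rtrunc_multiplier <- function(n, frac, lower = 0.01) {
  if (frac == 0) return(rep(1, n))
  out <- stats::rnorm(n, mean = 1, sd = frac)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean = 1, sd = frac)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Perturb a scenario's uncertain inputs
#'
#' Draws one multiplier per named input (from the current RNG state) and
#' applies it: `noise_db` rescales each exposure's level change, `persons`
#' rescales every beneficiary count, the others rescale their unit value or
#' unit cost. Unlisted inputs pass through unchanged.
#'
#' @param scenario a [green_wall_scenario()].
#' @param spec an [mc_spec()].
#' @return A perturbed `green_wall_scenario`.
#' @export
sample_perturbed_scenario <- function(scenario, spec = mc_spec()) {
  p <- spec$perturbations
  lo <- spec$lower_truncation
  m <- vapply(MC_INPUTS, function(k) rtrunc_multiplier(1, p[[k]], lo), numeric(1))
  s <- scenario
  s$amenity_params$unit_value <- s$amenity_params$unit_value * m[["amenity_unit_value"]]
  s$invest_unit_cost <- s$invest_unit_cost * m[["invest_unit_cost"]]
  s$maintenance_unit_cost <- s$maintenance_unit_cost * m[["maintenance_unit_cost"]]
  s$exposures <- lapply(s$exposures, function(e) {
    e$level_after <- e$level_before - (e$level_before - e$level_after) * m[["noise_db"]]
    e$persons <- e$persons * m[["persons"]]
    e
  })
  s$roster$resident_persons <- s$roster$resident_persons * m[["persons"]]
  s$roster$external_persons <- s$roster$external_persons * m[["persons"]]
  s
}

#' Monte Carlo simulation of the benefit-cost ratio
#'
#' Runs [run_cba()] on `draws` independently perturbed copies of the
#' scenario. The same `seed` reproduces the sample vector bit for bit.
#'
#' @param scenario a [green_wall_scenario()].
#' @param spec an [mc_spec()].
#' @param seed integer RNG seed.
#' @param cpi a [price_index_table()].
#' @return An object of class `mc_result`: `bc_samples`, `point_estimate`
#'   (deterministic B/C), `band_low`/`band_high` (empirical order-statistic
#'   quantiles at (1-band)/2 and 1-(1-band)/2), `band` and `draws`.
#' @export
simulate_bc <- function(scenario, spec = mc_spec(), seed = 1L,
                        cpi = default_cpi_table()) {
  point <- run_cba(scenario, cpi)$bc_ratio
  set.seed(as.integer(seed))
  samples <- vapply(seq_len(spec$draws), function(i) {
    run_cba(sample_perturbed_scenario(scenario, spec), cpi)$bc_ratio
  }, numeric(1))
  a <- (1 - spec$band) / 2
  q <- stats::quantile(samples, c(a, 1 - a), type = 1, names = FALSE)
  structure(list(scenario = scenario$name, bc_samples = samples,
                 point_estimate = point, band_low = q[1], band_high = q[2],
                 band = spec$band, draws = spec$draws, seed = as.integer(seed)),
            class = "mc_result")
}

#' Fraction of simulated ratios above a threshold
#'
#' @param result an `mc_result`.
#' @param threshold e.g. 1 for economic efficiency.
#' @return Fraction in \[0, 1\].
#' @export
share_above <- function(result, threshold = 1) {
  mean(result$bc_samples > threshold)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s: %d draws (seed %d)\n", x$scenario, x$draws, x$seed))
  cat(sprintf("  point B/C %.2f; median %.2f; %g%% band [%.2f, %.2f]; share > 1: %.1f%%\n",
              x$point_estimate, stats::median(x$bc_samples), 100 * x$band,
              x$band_low, x$band_high, 100 * share_above(x, 1)))
  invisible(x)
}

#' Read the `mc` block of a scenario file
#'
#' @param path scenario YAML path.
#' @return An [mc_spec()] (defaults if the file has no `mc` block).
#' @export
mc_spec_from_scenario_file <- function(path) {
  raw <- yaml::read_yaml(path)
  m <- raw$mc
  if (is.null(m)) return(mc_spec())
  args <- list(draws = m$draws %||% 10000,
               lower_truncation = m$lower_truncation %||% 0.01,
               band = m$band %||% 0.90)
  if (!is.null(m$perturbations)) args$perturbations <- unlist(m$perturbations)
  do.call(mc_spec, args)
}
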