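# Synthetic-data generators with known ground truth. Every generated object
# is a fully valid pipeline input (it passes the same validators as the
# packaged fixtures), and each generator emits the latent truth — or an
# independently computed expected result — alongside, so pipeline bugs
# cannot self-validate.

#' Generate a synthetic hedonic study collection
#'
#' Studies are generated around a known true unit value: each study's
#' observed premium is drawn so that its implied base-year unit value is
#' Normal(true_unit_value, SE_g^2), with SE_g = (relative SE drawn from
#' `se_range`) x true_unit_value. Premiums are produced on the percentage
#' scale and pushed backwards through the real transfer chain (annuity,
#' currency, CPI), so the generated records exercise the same code paths as
#' real review data. Uncertainty metadata is written so that the pooling
#' stage's imputation recovers SE_g: interval studies get a 95% interval of
#' half-width 1.96 x SE_g (on the premium scale), reported-SE studies store
#' the matching relative SE, and "none" studies are generated with relative
#' SE 0.5, the value the imputation rule will assume.
#'
#' @param true_unit_value latent unit value, EUR/m2/household/yr, > 0.
#' @param n_studies number of studies G.
#' @param se_range length-2 range of relative SEs, both > 0.
#' @param kind_mix named proportions for `interval`, `reported-se`, `none`;
#'   must sum to 1.
#' @param seed integer RNG seed.
#' @param config a [transfer_config()] supplying the currency/CPI tables the
#'   records draw their (currency, year) assignments from.
#' @return A list: `studies` (list of [hedonic_study()]), `truth`
#'   (data.frame with `study_id`, `true_unit_value`, `se`), and the spec
#'   fields echoed back.
#' @export
gen_hedonic_studies <- function(true_unit_value, n_studies,
                                se_range = c(0.1, 0.6),
                                kind_mix = c("interval" = 0.4,
                                             "reported-se" = 0.4,
                                             "none" = 0.2),
                                seed = 1L, config = transfer_config()) {
  gw_check_number(true_unit_value, "true_unit_value", min = 0, strict = TRUE)
  gw_check_number(n_studies, "n_studies", min = 1)
  if (any(se_range <= 0) || se_range[1] > se_range[2]) {
    gw_stop("`se_range` must be an increasing pair of positive values",
            "gwcba_invalid_parameter")
  }
  if (abs(sum(kind_mix) - 1) > 1e-8) {
    gw_stop("`kind_mix` proportions must sum to 1", "gwcba_invalid_parameter")
  }
  set.seed(as.integer(seed))
  fx_rows <- config$fx$rates
  kinds <- sample(names(kind_mix), n_studies, replace = TRUE, prob = kind_mix)
  studies <- vector("list", n_studies)
  truth <- data.frame(study_id = character(n_studies),
                      true_unit_value = numeric(n_studies),
                      se = numeric(n_studies), stringsAsFactors = FALSE)
  for (i in seq_len(n_studies)) {
    kind <- kinds[i]
    ub <- if (kind == "interval") min(se_range[2], 0.45) else se_range[2]
    rel <- if (kind == "none") 0.5 else stats::runif(1, min(se_range[1], ub), ub)
    se_abs <- rel * true_unit_value
    # draw the observed unit value; redraw until the implied premium is
    # positive (records with premium <= 0 are not valid inputs)
    y <- -1
    while (y <= 0.01 * true_unit_value) {
      y <- stats::rnorm(1, true_unit_value, se_abs)
    }
    fx_row <- fx_rows[sample.int(nrow(fx_rows), 1), ]
    price_kind <- sample(c("property-price", "annual-rent"), 1)
    area <- stats::runif(1, 20, 80)
    price <- if (price_kind == "property-price") {
      stats::runif(1, 5e4, 5e5)
    } else {
      stats::runif(1, 3e3, 3e4)
    }
    rec0 <- hedonic_study(study_id = sprintf("synth%03d", i),
                          data_year = fx_row$year, location = "synthetic",
                          currency = fx_row$currency, price_kind = price_kind,
                          price = price, premium_lo = 1, premium_hi = 1,
                          premium_base = "annuity", greenery_area = area,
                          uncertainty = "none")
    # unit value per percentage point of premium; invert for the target y
    k <- to_unit_value(rec0, config)$unit_value
    mid <- y / k
    args <- list(study_id = rec0$study_id, data_year = rec0$data_year,
                 location = "synthetic", currency = rec0$currency,
                 price_kind = price_kind, price = price,
                 premium_base = "annuity", greenery_area = area)
    if (kind == "interval") {
      hw <- 1.96 * (se_abs / k)   # half-width on the premium scale
      args <- c(args, list(premium_lo = mid - hw, premium_hi = mid + hw,
                           uncertainty = "interval"))
      if (args$premium_lo <= 0) {  # keep the record valid; fall back to reported-se
        args$premium_lo <- args$premium_hi <- mid
        args$uncertainty <- "reported-se"
        args$rel_se <- se_abs / y
      }
    } else if (kind == "reported-se") {
      # stored relative to the observed value so the imputed SE equals se_abs
      args <- c(args, list(premium_lo = mid, premium_hi = mid,
                           uncertainty = "reported-se", rel_se = se_abs / y))
    } else {
      args <- c(args, list(premium_lo = mid, premium_hi = mid,
                           uncertainty = "none"))
      se_abs <- 0.5 * y  # what the imputation rule will assume
    }
    studies[[i]] <- do.call(hedonic_study, args)
    truth$study_id[i] <- rec0$study_id
    truth$true_unit_value[i] <- true_unit_value
    truth$se[i] <- se_abs
  }
  list(studies = studies, truth = truth, true_unit_value = true_unit_value,
       n_studies = as.integer(n_studies), se_range = se_range,
       kind_mix = kind_mix, seed = as.integer(seed))
}

#' Generate a random CBA scenario with an independent expected result
#'
#' Draws geometry, costs, exposures and rosters uniformly from the given
#' ranges and computes the expected annual line items and benefit-cost ratio
#' with deliberately duplicated straight-line arithmetic (explicit discount
#' loops and multiplications that share no code with [run_cba()]), so the
#' two routes check each other.
#'
#' @param seed integer RNG seed.
#' @param area_range,invest_range,maintenance_range,db_range,persons_range
#'   length-2 positive ranges for the respective inputs.
#' @param cpi a [price_index_table()] used by both routes.
#' @return A list: `scenario` (a [green_wall_scenario()]) and `expected`
#'   (list with the oracle's annual line items and `bc_ratio`).
#' @export
gen_scenario <- function(seed = 1L, area_range = c(20, 500),
                         invest_range = c(100, 1000),
                         maintenance_range = c(5, 60),
                         db_range = c(0.5, 8), persons_range = c(10, 300),
                         cpi = default_cpi_table()) {
  for (r in list(area_range, invest_range, maintenance_range, db_range,
                 persons_range)) {
    if (any(r <= 0) || r[1] > r[2]) {
      gw_stop("all ranges must be positive increasing pairs", "gwcba_invalid_parameter")
    }
  }
  set.seed(as.integer(seed))
  area <- stats::runif(1, area_range[1], area_range[2])
  invest <- stats::runif(1, invest_range[1], invest_range[2])
  maint <- stats::runif(1, maintenance_range[1], maintenance_range[2])
  lifetime <- sample(c(5, 8, 10, 20, 40), 1)
  rate <- stats::runif(1, 0.01, 0.07)
  horizon <- 40
  db <- stats::runif(1, db_range[1], db_range[2])
  before <- stats::runif(1, 50, 68)
  persons_noise <- stats::runif(1, persons_range[1], persons_range[2])
  res_persons <- stats::runif(1, persons_range[1], persons_range[2])
  ext_persons <- stats::runif(1, 0, 30)
  amenity_uv <- stats::runif(1, 0.2, 4)
  side <- sample(c("quiet", "most-exposed"), 1)
  scenario <- green_wall_scenario(
    name = sprintf("synthetic_seed%d", as.integer(seed)),
    area = area, invest_unit_cost = invest, invest_lifetime = lifetime,
    maintenance_unit_cost = maint, cost_year = 2011,
    project_discount = discount_spec(rate, horizon, "start-of-year"),
    project_year = 2011,
    exposures = list(facade_exposure(before, before - db, side, persons_noise)),
    roster = beneficiary_roster(res_persons, ext_persons),
    noise_params = noise_valuation_params(),
    amenity_params = amenity_params(amenity_uv, 2010)
  )
  list(scenario = scenario,
       expected = oracle_cba(area, invest, lifetime, maint, rate, horizon,
                             before, db, side, persons_noise,
                             res_persons + ext_persons, amenity_uv, cpi))
}

# Straight-line arithmetic oracle for a generated scenario. Intentionally
# independent of the finance/cba modules: discount sums are explicit loops,
# the annuity factor is a power series, and the clamping band is written out
# long-hand.
#' @noRd
oracle_cba <- function(area, invest, lifetime, maint, rate, horizon, before,
                       db, side, persons_noise, persons_amenity, amenity_uv,
                       cpi) {
  idx <- cpi$index
  f2011 <- idx[["2011"]] / idx[["2002"]]
  a2011 <- idx[["2011"]] / idx[["2010"]]
  # annuity-due factor as an explicit sum of discount factors for t = 0..T-1
  af <- 0
  for (t in 0:(horizon - 1)) af <- af + (1 + rate)^(-t)
  pv <- 0
  t <- 0
  while (t < horizon) {
    pv <- pv + invest * (1 + rate)^(-t)
    t <- t + lifetime
  }
  annual_investment <- area * pv / af
  annual_maintenance <- area * maint
  after <- before - db
  hi <- if (before < 71) before else 71
  lo <- if (after > 45) after else 45
  eff <- hi - lo
  if (eff < 0) eff <- 0
  if (side == "quiet") eff <- eff * 0.3
  noise_benefit <- persons_noise * eff * 10.095 * f2011
  amenity_benefit <- area * amenity_uv * a2011 * persons_amenity
  total_benefits <- noise_benefit + amenity_benefit
  total_costs <- annual_investment + annual_maintenance
  list(annual_investment = annual_investment,
       annual_maintenance = annual_maintenance,
       noise_benefit = noise_benefit, amenity_benefit = amenity_benefit,
       total_benefits = total_benefits, total_costs = total_costs,
       bc_ratio = total_benefits / total_costs)
}
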