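# Published reference line items for the two demonstration walls (high and
# low amenity unit value). B/C references are recomputed from these printed
# integers; computed ratios must land within +/-0.01 of them.
printed_items <- list(
  demo_3m = list(invest = 3301, maint = 1450, noise = 1932, amenity = 16935),
  demo_19m = list(invest = 20999, maint = 9225, noise = 1761, amenity = 118698),
  demo_3m_low = list(invest = 3301, maint = 1450, noise = 1932, amenity = 4234),
  demo_19m_low = list(invest = 20999, maint = 9225, noise = 1761, amenity = 29674)
)

test_that("annualised costs reproduce the published line items", {
  c3 <- annual_costs(load_fixture("demo_3m"))
  expect_equal(round(c3$annual_investment), 3301)
  expect_equal(c3$annual_maintenance, 58 * 25)
  c19 <- annual_costs(load_fixture("demo_19m"))
  expect_lte(abs(c19$annual_investment - 20999), 1)
  expect_equal(c19$annual_maintenance, 369 * 25)
})

test_that("all four demonstration CBAs reproduce line items and B/C ratios", {
  for (name in names(printed_items)) {
    ref <- printed_items[[name]]
    res <- run_cba(load_fixture(name))
    expect_rel(res$annual_investment, ref$invest, 0.01)
    expect_rel(res$noise_benefit, ref$noise, 0.01)
    expect_rel(res$amenity_benefit, ref$amenity, 0.01)
    ref_bc <- (ref$noise + ref$amenity) / (ref$invest + ref$maint)
    expect_lt(abs(res$bc_ratio - ref_bc), 0.01)
    expect_equal(res$total_benefits, res$noise_benefit + res$amenity_benefit)
    expect_equal(res$total_costs, res$annual_investment + res$annual_maintenance)
  }
})

test_that("published two-decimal B/C ratios are recovered", {
  expect_equal(round_ratio(run_cba(load_fixture("demo_3m"))$bc_ratio), 3.97)
  expect_equal(round_ratio(run_cba(load_fixture("demo_19m"))$bc_ratio), 3.99)
  expect_equal(round_ratio(run_cba(load_fixture("demo_3m_low"))$bc_ratio), 1.30)
  expect_equal(round_ratio(run_cba(load_fixture("demo_19m_low"))$bc_ratio), 1.04)
})

test_that("amenity dominates noise by roughly one and two orders of magnitude", {
  s3 <- benefit_share(run_cba(load_fixture("demo_3m")))
  s19 <- benefit_share(run_cba(load_fixture("demo_19m")))
  expect_equal(s3, 16935 / 1932, tolerance = 0.01)
  expect_equal(s19, 118698 / 1761, tolerance = 0.01)
})

test_that("B/C ratio is scale-free in joint scaling and linear in benefits", {
  s <- toy_scenario()
  res <- run_cba(s)
  # double all unit prices and costs: benefits and costs double, ratio fixed
  s2 <- s
  s2$invest_unit_cost <- s$invest_unit_cost * 2
  s2$maintenance_unit_cost <- s$maintenance_unit_cost * 2
  s2$amenity_params$unit_value <- s$amenity_params$unit_value * 2
  s2$noise_params$unit_price <- s$noise_params$unit_price * 2
  res2 <- run_cba(s2)
  expect_equal(res2$bc_ratio, res$bc_ratio, tolerance = 1e-12)
  expect_equal(res2$total_costs, 2 * res$total_costs, tolerance = 1e-12)
  # doubling only benefit unit prices doubles the ratio
  s3 <- s
  s3$amenity_params$unit_value <- s$amenity_params$unit_value * 2
  s3$noise_params$unit_price <- s$noise_params$unit_price * 2
  expect_equal(run_cba(s3)$bc_ratio, 2 * res$bc_ratio, tolerance = 1e-12)
})

test_that("area scaling moves costs linearly at a fixed cost mix", {
  s <- toy_scenario(area = 100)
  s2 <- toy_scenario(area = 200)
  c1 <- annual_costs(s)
  c2 <- annual_costs(s2)
  expect_equal(c2$annual_investment, 2 * c1$annual_investment, tolerance = 1e-12)
  expect_equal(c2$annual_maintenance / c2$annual_investment,
               c1$annual_maintenance / c1$annual_investment, tolerance = 1e-12)
})

test_that("degenerate scenarios are rejected or behave consistently", {
  s <- toy_scenario()
  s$invest_unit_cost <- 0
  s$maintenance_unit_cost <- 0
  expect_error(run_cba(s), class = "gwcba_undefined_ratio")
  # benefits engineered to equal costs give a ratio of exactly 1
  base <- run_cba(toy_scenario())
  s1 <- toy_scenario()
  s1$amenity_params$unit_value <- s1$amenity_params$unit_value *
    (base$total_costs - base$noise_benefit) / base$amenity_benefit
  expect_equal(run_cba(s1)$bc_ratio, 1, tolerance = 1e-12)
})

test_that("scenario YAML round-trips losslessly", {
  path <- tempfile(fileext = ".yaml")
  s <- load_fixture("demo_19m")
  write_scenario(s, path, mc = mc_spec(draws = 123))
  s2 <- read_scenario(path)
  expect_equal(s2, s)
  expect_identical(mc_spec_from_scenario_file(path)$draws, 123L)
  unlink(path)
})
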