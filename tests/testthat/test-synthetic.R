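test_that("generators are deterministic and emit valid pipeline inputs", {
  g1 <- gen_hedonic_studies(10, 20, seed = 42)
  g2 <- gen_hedonic_studies(10, 20, seed = 42)
  expect_equal(g1, g2)
  expect_length(g1$studies, 20)
  for (rec in g1$studies) {
    expect_s3_class(rec, "hedonic_study")
    expect_gt((rec$premium_lo + rec$premium_hi) / 2, 0)
  }
  # generated records run through the whole transfer/pooling chain
  est <- weighted_estimates(g1$studies)
  expect_true(all(est$se > 0))
  s1 <- gen_scenario(seed = 5)
  s2 <- gen_scenario(seed = 5)
  expect_equal(s1, s2)
})

test_that("imputed SEs recover the generator's latent SEs", {
  g <- gen_hedonic_studies(10, 40, seed = 9)
  est <- weighted_estimates(g$studies)
  kinds <- vapply(g$studies, function(s) s$uncertainty, character(1))
  anchored <- kinds != "none"
  # interval and reported-se records encode the truth-anchored SE exactly
  expect_equal(est$se[anchored], g$truth$se[anchored], tolerance = 1e-9)
})

test_that("pooling a synthetic collection recovers the true unit value", {
  # recovery uses kinds that can encode an arbitrary latent SE from
  # se_range (interval / reported); the "none" kind pins its SE to half the
  # *observed* value, which makes the weights heavy-tailed by construction
  # and is exercised separately below
  truth <- 10
  reps <- 150
  mix <- c("interval" = 0.5, "reported-se" = 0.5, "none" = 0)
  means <- numeric(reps)
  pooled_se <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- gen_hedonic_studies(truth, 50, se_range = c(0.1, 0.6), kind_mix = mix,
                             seed = 1000 + r)
    m <- meta_weighted_mean(weighted_estimates(g$studies))
    means[r] <- m$weighted_mean
    pooled_se[r] <- m$pooled_se
  }
  # replicate mean within 2 analytic pooled-SEs of truth, and the empirical
  # spread of the estimator matching the analytic pooled SE
  expect_lt(abs(mean(means) - truth), 2 * mean(pooled_se))
  expect_equal(stats::sd(means), mean(pooled_se), tolerance = 0.15)
})

test_that("the 50%-imputation rule attenuates pooled means of noisy collections", {
  # with SE imputed as half the observed value, weights are 4/y^2: small
  # draws dominate and the pooled mean falls below the truth (the same
  # mechanism that lets one low outlier dominate the packaged review table)
  truth <- 10
  means <- vapply(1:60, function(r) {
    g <- gen_hedonic_studies(truth, 50,
                             kind_mix = c("interval" = 0, "reported-se" = 0,
                                          "none" = 1), seed = 3000 + r)
    meta_weighted_mean(weighted_estimates(g$studies))$weighted_mean
  }, numeric(1))
  expect_lt(mean(means), truth)
})

test_that("degenerate synthetic collections behave analytically", {
  tiny <- gen_hedonic_studies(7.5, 12, se_range = c(1e-6, 1e-6),
                              kind_mix = c("interval" = 0.5,
                                           "reported-se" = 0.5, "none" = 0),
                              seed = 3)
  m <- meta_weighted_mean(weighted_estimates(tiny$studies))
  expect_equal(m$weighted_mean, 7.5, tolerance = 1e-4)
  single <- gen_hedonic_studies(4, 1, seed = 8)
  est <- weighted_estimates(single$studies)
  expect_equal(meta_weighted_mean(est)$weighted_mean, est$effect[1])
})

test_that("the CBA pipeline agrees with the independent arithmetic oracle", {
  for (seed in 1:30) {
    gs <- gen_scenario(seed = seed)
    res <- run_cba(gs$scenario)
    for (field in c("annual_investment", "annual_maintenance", "noise_benefit",
                    "amenity_benefit", "total_benefits", "total_costs",
                    "bc_ratio")) {
      expect_equal(res[[field]], gs$expected[[field]], tolerance = 1e-9)
    }
  }
})

test_that("a scenario with no benefits has a zero ratio", {
  s <- toy_scenario(amenity_unit = 0)
  s$exposures <- list(facade_exposure(44, 40, "quiet", 100))  # below cut-off
  expect_identical(run_cba(s)$bc_ratio, 0)
})

test_that("synthetic studies round-trip through the CSV interface", {
  g <- gen_hedonic_studies(10, 10, seed = 21)
  path <- tempfile(fileext = ".csv")
  write_studies(g$studies, path)
  back <- read_studies(path)
  expect_length(back, 10)
  orig_uv <- vapply(g$studies, function(r) to_unit_value(r)$unit_value, numeric(1))
  back_uv <- vapply(back, function(r) to_unit_value(r)$unit_value, numeric(1))
  expect_equal(back_uv, orig_uv, tolerance = 1e-12)
  unlink(path)
})
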