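Package: greenwallcba
Title: Monetised Valuation of Green Walls as Urban Soundscape Measures
Version: 1.0.0
Authors@R:
    person("Transport & Environment Economics Lab", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for the economic appraisal of vegetated ("green") walls
    and roofs as combined noise-control and amenity measures. Implements
    benefit transfer from published hedonic-pricing studies to per-square-metre
    amenity unit values (annuitisation, currency conversion, consumer-price-index
    updating), fixed-effect inverse-variance meta-analytic pooling with
    standard-error imputation, monetisation of quiet-side noise-level reductions
    with a decibel cut-off, validity cap and quiet-side conversion factor,
    scenario cost-benefit analysis with annualised costs and benefit-cost
    ratios, and Monte Carlo sensitivity analysis with truncated-normal input
    perturbation. Ships the worked demonstration inputs as plain-text fixtures
    and a synthetic-data generator with independent arithmetic oracles for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
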