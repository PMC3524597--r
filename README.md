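# greenwallcba

Economic appraisal of vegetated ("green") walls and roofs as combined
noise-control and amenity measures.

Green walls at the entrance of an inner courtyard reduce traffic noise on the
*quiet* side of a block of flats and improve its looks. Standard noise
appraisal values decibel changes only on the most exposed facade and ignores
aesthetics entirely, so such measures look uneconomic. This package
implements the full monetisation chain that corrects both omissions, for
environmental economists and planners running pilot ("mini") cost-benefit
analyses:

* **Benefit transfer** — published hedonic-pricing premiums for urban
  greenery are converted to a common unit value *Y<sub>g</sub>* (EUR per m²
  per household per year, base-year prices) via annuitisation
  (*a(r,T) = (1−(1+r)<sup>−T</sup>)/r*, 5%/50 yr for property), currency
  conversion and CPI updating.
* **Inverse-variance meta-analysis** — fixed-effect pooling with weights
  *W<sub>g</sub> = 1/SE<sub>g</sub>²*, imputing SEs from reported intervals
  (read as 95% CIs) or, failing that, as 50% of the point estimate; with
  leave-one-out influence analysis.
* **Noise monetisation** — EUR/person/dB/yr unit pricing with a 45 dB(A)
  cut-off, a 71 dB(A) validity cap, and a 0.3 quiet-side conversion factor
  (3 quiet-side dB count as 1 most-exposed dB).
* **Scenario CBA** — annualised recurring investment (annuity-due, 3%/40 yr)
  plus maintenance against the two benefit streams; benefit-cost ratio at
  full precision.
* **Monte Carlo sensitivity** — truncated-normal multiplicative perturbation
  (amenity ±50%, other benefits/costs ±30%, beneficiary counts ±15%) with a
  90% quantile band.
* **Synthetic data** — generators with known ground truth and an independent
  arithmetic oracle, so every stage is testable offline.

The demonstration inputs (an eight-study hedonic review table and two
green-wall scenarios, 58 m² and 369 m², each with a high and a low amenity
unit value) ship as plain-text fixtures under `inst/extdata/`.

## Worked example

```r
library(greenwallcba)

# 1. value transfer: review studies -> per-m2 unit values
tab <- transfer_table(load_fixture("table1"))
data.frame(study = tab$study_id, unit_value = round(tab$unit_value, 2))
#>                      study unit_value
#> 1                 peck1999      20.88
#> 2                 hunt2008      17.90
#> 3            gao2007_tokyo       3.46
#> 4       gao2007_kitakyushu       0.69
#> 5             ichihara2010      17.12
#> 6           desrosiers2002       3.78
#> 7 tomalty2010_recreational      63.47
#> 8   tomalty2010_productive      22.21

# 2. inverse-variance pooling
meta_weighted_mean(weighted_estimates(load_fixture("table1")))
#> <meta_result> 8 studies: weighted mean 1.226 (pooled SE 0.376)
#>   largest relative weight: gao2007_kitakyushu (89.4%)

# 3. cost-benefit analysis of the 3 m demonstration wall (58 m2)
run_cba(load_fixture("demo_3m"))
#> <cba_result> demo_3m
#>                                  Benefits      Costs
#>   Investment costs                             3,301
#>   Maintenance costs                            1,450
#>   Noise attenuation benefits        1,932
#>   Amenity/aesthetic benefits       16,935
#>   Total                            18,867      4,751
#>   B/C ratio: 3.97 (full precision 3.971499)

# 4. Monte Carlo sensitivity (10,000 draws)
simulate_bc(load_fixture("demo_3m"), mc_spec(), seed = 1)
#> <mc_result> demo_3m: 10000 draws (seed 1)
#>   point B/C 3.97; median 3.97; 90% band [1.26, 8.68]; share > 1: 97.2%
```

Reading the numbers: the simple mean of the eight transferred unit values is
18.7 EUR/m²/household/yr (12.3 excluding the largest), but inverse-variance
pooling collapses to 1.2 because one low, nominally precise estimate carries
~89% of the weight; dropping it gives 5.8, i.e. 2.4 EUR per person. Applied
to the 58 m² wall, amenity benefits (16,935 EUR/yr for 118 beneficiaries)
dwarf the quiet-side noise benefits (1,932 EUR/yr for 115 residents,
4.5 dB × 0.3), and the wall returns 3.97 benefit-per-cost-euro; with the
outlier-dominated unit value instead, the ratio drops to about 1.3 (and 1.04
for the 369 m² wall) — the amenity unit value decides economic efficiency.
The 90% simulation band stays above 1 for the high-amenity case.

The full pipeline (transfer → pooling → four CBAs → Monte Carlo, with JSON +
CSV reports) is one call — `run_pipeline("out/", seed = 1)` — or one CLI
command:

```sh
Rscript inst/cli/greenwallcba report --out out --seed 1
# subcommands: transfer | weight | cba | mc | synth | report
```

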