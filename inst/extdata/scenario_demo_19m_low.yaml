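# Low-amenity variant of the 19.2 m demonstration project (see the 3 m low
# variant for the 0.6 vs 0.5 unit-value note).
schema: greenwallcba/scenario/v1
name: demo_19m_low
area_m2: 369
project_year: 2011
costs:
  invest_unit_cost: 500
  invest_lifetime: 10
  maintenance_unit_cost: 25
  cost_year: 2011
discounting:
  rate: 0.03
  horizon: 40
  timing: start-of-year
exposures:
  - side: quiet
    level_before: 59.3
    level_after: 55.2
    persons: 115
noise_valuation:
  unit_price: 10.095
  price_year: 2002
  validity_cap: 71
  cutoff: 45
  quiet_side_factor: 0.3
amenity:
  unit_value: 0.6
  value_year: 2010
  roster:
    resident_persons: 115
    external_persons: 15
mc:
  draws: 10000
  perturbations:
    amenity_unit_value: 0.50
    noise_db: 0.30
    invest_unit_cost: 0.30
    maintenance_unit_cost: 0.30
    persons: 0.15
  lower_truncation: 0.01
  band: 0.90
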