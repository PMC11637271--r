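# Example model configuration.  Any omitted field falls back to the
# package's base-case default; shown here are the headline inputs.
# The life table may be an inline mapping (age/q/ex sequences) or a CSV
# path relative to this file; this one is a synthetic Gompertz stub
# scaled to a remaining life expectancy of 28 years at age 40 -- replace
# it with a real national life table for applied analyses.
settings:
  starting_age: 40
  horizon: 10
  discount_rate: 0.03
  half_cycle_correction: true
strategies:
  ac:
    provider: AC
    cost_per_procedure: 149
    p_recurrence: 0.0092
    p_contralateral: 0.0038
  md:
    provider: MD
    cost_per_procedure: 163
    p_recurrence: 0.0686
    p_contralateral: 0.0038
disability_weights:
  none: 0.0
  mild: 0.0110
  moderate: 0.1140
  severe: 0.3240
premature_death:
  p_complication: 0.0056
  p_mortality_given_complication: 0.20
life_table: life_table_synthetic_stub.csv
thresholds:
  gdp_per_capita: 476
  wtp: 1428
budget_impact:
  population: 2566837
  population_growth: 0.021
  prevalence: 0.086
  incidence_per_100k: 1250
  repair_rate_per_100k: 470
  share_md: 0.68
  share_ac: 0.32
  training_cost: 2000
  renovation_cost: 12000
  providers_per_facility: 3
  repairs_per_provider_year: 27.5
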