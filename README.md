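# herniaCEA

Economic evaluation of task-shared elective inguinal hernia repair in
Sierra Leone, for health economists and surgical-policy analysts: a
four-state Markov cohort model of hernia disease with DALY outcomes and
discounted healthcare-system costs, pairwise incremental
cost-effectiveness with dominance and willingness-to-pay classification,
deterministic (tornado) and probabilistic sensitivity analyses with
cost-effectiveness acceptability curves, and a national budget-impact
projection of clearing the surgical backlog through task-sharing by
associate clinicians (ACs) and non-specialist medical doctors (MDs).

## The model

An annual-cycle cohort starts at age 40 with a symptomatic primary
inguinal hernia and moves between four states — *new hernia*,
*recurrent hernia*, *repaired*, *dead* — under background age-specific
mortality q(a), an untreated premature-death risk
p = p(complication) × p(death | complication) = 0.0056 × 0.20 = 0.00112
per year, provider-specific annual recurrence (AC 0.92%, MD 6.86%) and a
0.38% contralateral risk. Health outcomes are DALYs:

    DALY = YLD + YLL

with YLD accrued per cycle as occupancy-weighted disability (Inguinal
Pain Questionnaire scores mapped to disability weights by band: mild
0.0110, moderate 0.1140, severe 0.3240) and YLL from premature hernia
deaths valued at remaining life expectancy. Costs (2023 USD: AC 149, MD
163 per procedure, re-repairs on recurrence) and health effects are
discounted at 3%/year over 10 years with half-cycle correction. The
incremental cost-effectiveness ratio of strategy b against comparator a
is

    ICER = (C_b − C_a) / (E_a − E_b)   [USD per DALY averted]

judged against WHO-style thresholds (very cost-effective < 1× GDP per
capita = USD 476; cost-effective < 3× GDP = USD 1,428). The
budget-impact projection tracks the national backlog
(prevalence 8.6%, incidence 1,250/100k/yr, baseline repair rate
470/100k/yr) and costs its elimination (68% MD / 32% AC task-sharing mix,
USD 2,000 training per provider, USD 12,000 renovation per
three-provider facility).

An individual-level microsimulation oracle and a synthetic trial-cohort
generator/estimator pair validate the cohort engine end to end; see the
methods vignette (`vignettes/hernia-cea-methods.Rmd`) for the modelling
conventions and their rationale.

## Worked example

```r
library(herniaCEA)
cea <- hernia_cea(default_parameters())
print(cea)
```

```
Cost-effectiveness of task-shared inguinal hernia repair
Base case
                                   none       MD       AC
  Total cost ($)                      0      252      164
  Total DALYs                      0.75     0.11     0.08
  Incremental cost ($)                -      252      164   (AC vs MD: -88)
  Incremental DALYs averted           -     0.64     0.67   (AC vs MD: 0.03)
  ICER ($/DALY averted)               -      392      243   (AC vs MD: dominant)
...
Thresholds: GDP/capita 476 USD (very cost-effective), WTP 1428 USD/DALY averted
```

Untreated, an adult man with a symptomatic hernia accrues 0.75 DALYs
over the decade; repair reduces that to 0.08 (AC) or 0.11 (MD) for
discounted per-patient costs of USD 164 and 252, giving ICERs of 243 and
392 USD per DALY averted — both far below the GDP-per-capita threshold,
i.e. very cost-effective — while AC repair dominates MD repair (cheaper
and at least as effective, driven by the lower recurrence rate). ICERs
fall further with pre-operative severity (65 USD/DALY averted for severe
pain under ACs).

The budget side:

```r
open_budget_scenario(default_parameters()$budget_impact)
```

```
Budget-impact projection (open_budget), 2024-2033
  initial backlog 220748; 10-year backlog (initial + incidence) 581097
  repairs delivered 581097; final-year backlog 0
  cumulative cost USD 104.8 million
  providers trained 2114, facilities renovated 705
```

Clearing the decade's backlog of ~581,000 repairs costs ~USD 105
million, requiring ~2,100 newly trained providers in ~700 renovated
facilities. Capped budgets of USD 10M/80M address ~10%/76% of the
backlog (`capped_budget_scenario`).

Sensitivity analyses: `one_way_dsa()` (tornado; the ICER is most
sensitive to the cost per procedure), `run_psa()` + `ceac()`
(probabilistic analysis and acceptability curves). Report-writer
functions (`write_cea_report`, `write_dsa_report`, `write_psa_report`,
`write_bia_report`) emit CSV/JSON outputs with JSON run manifests.
Parameters load from YAML (`load_parameters`; see
`inst/extdata/example_config.yaml`), with absent fields filled from the
published defaults.

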