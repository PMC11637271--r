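---
title: "Modelling the cost-effectiveness of task-shared inguinal hernia repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of task-shared inguinal hernia repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herniaCEA)
```

## The decision problem

Sierra Leone carries a large backlog of untreated inguinal hernia in
adult men, and most elective repairs are delivered through surgical
task-sharing: open mesh repair by associate clinicians (ACs, mid-level
providers with structured postgraduate surgical training) and
non-specialist medical doctors (MDs). `herniaCEA` evaluates that
strategy from the healthcare-system perspective along two axes:

1. **Cost-effectiveness**: cost per disability-adjusted life year (DALY)
   averted of AC and MD repair, each against no treatment and against
   one another, over a 10-year horizon.
2. **Budget impact**: the undiscounted national cost of expanding repair
   capacity to clear the backlog over a decade, under open and capped
   budgets.

## The Markov cohort model

The cohort starts at age 40 with a symptomatic primary inguinal hernia
and moves between four exclusive states on annual cycles: *new hernia*,
*recurrent hernia*, *repaired* and *death* (absorbing). Transitions are
driven by:

* background age-specific mortality $q(a)$ from the life table;
* the premature-death risk of an untreated hernia,
  $p_{pd} = p_{compl} \times p_{mort|compl} = 0.0056 \times 0.20 =
  0.00112$ per year (acute incarceration/strangulation and its case
  fatality);
* annual recurrence after repair ($0.92\%$ for ACs, $6.86\%$ for MDs)
  and a $0.38\%$ annual contralateral-hernia risk.

Competing risks within a cycle combine as independent events applied
multiplicatively (background mortality first; survivors are then exposed
to recurrence, and non-recurrent survivors to contralateral occurrence),
which keeps every row of the transition matrix stochastic by
construction.

### Timing conventions

Three conventions are deliberate model choices, each configurable in
`settings`:

* **Treatment timing.** Trial outcomes (pain, recurrence) were measured
  one year after surgery, so the treated cohort spends cycle 1 at
  pre-operative disability and is in the repaired state from cycle 2;
  the procedure cost is charged at time 0. First-year recurrence applies
  at the first cycle boundary. Recurrent and contralateral hernias spend
  one full cycle at pre-operative pain and are re-repaired at the same
  provider's procedure cost, charged at entry into that cycle and
  discounted.
* **State membership** (`state_membership`). A cycle's disability is
  valued at the occupancy at the *start* of the cycle
  (`"cycle_start"`, the default): a patient who transitions out of a
  state still lived through the year that the cycle represents. This is
  what makes a one-cycle transient (the pre-operative year, a recurrence
  year) count in full, and it is the convention that reconciles the
  repaired-arm DALY totals with the cost totals simultaneously. The
  textbook occupancy trapezoid — membership as the average of the
  start and end boundary, under which a one-cycle transient counts half —
  is available as `"midpoint"` and via `apply_half_cycle_correction()`.
* **Half-cycle correction and discounting.** With the correction on
  (default), each cycle's accrual is valued at the average of its start-
  and end-boundary discount factors: a fully surviving 10-year cohort at
  3% accrues $\tfrac12\sum_t \left[(1.03)^{-(t-1)} + (1.03)^{-t}\right]
  = 8.658$ discounted person-years rather than the end-timed annuity
  $8.530$. Without the correction, `discount_timing` selects start-,
  mid- or end-cycle discounting. One-off event costs are point outlays
  and are never half-cycle averaged.

## Health outcomes

DALYs are the sum of years lived with disability (YLD) and years of life
lost (YLL), both discounted at 3% per year.

**YLD** accrues per cycle as occupancy-weighted disability. Pain on the
1–7 Inguinal Pain Questionnaire (IPQ) maps to Global Burden of Disease
style disability weights by band: no pain (IPQ 1) $\to 0$, mild (2–3)
$\to 0.0110$, moderate (4–5) $\to 0.1140$, severe (6–7) $\to 0.3240$.
Hernia states carry the pre-operative pain mix, the repaired state the
post-operative mix (default: fully resolved, i.e. weight 0, with a
configurable chronic-pain fraction). A formulation that multiplies the
disability weight directly by remaining life expectancy at surgery is
available (`compute_yld(..., method = "life_expectancy")`) but is
inconsistent with a 10-year horizon and is not used in reports.

**YLL** arises only from premature hernia deaths in untreated states.
Background deaths accrue no YLL — a deliberate convention, since the
comparison concerns hernia-attributable burden; treating all-cause death
as lost life-years would swamp the condition-specific signal. Each
premature death is valued at the remaining life expectancy at the age of
death taken from the life table, as a stream discounted from the death
time (`yll_convention = "full_remaining_LE_discounted"`, the default;
standard DALY practice). A `"horizon_capped"` alternative counts only
years inside the modelled decade; both conventions differ by well under
a tenth of a DALY in the base case.

### The calibrated pre-operative pain mix

The base-case pre-operative pain distribution of the source trial is not
published. It is therefore a required configuration field whose shipped
default is calibrated once: `calibrate_pain_mix()` solves for the
moderate fraction of a mild/moderate mixture such that the untreated
cohort accrues 0.75 DALYs over the decade (the published no-repair
total), giving a moderate fraction of 0.5841 (implied average disability
weight $\approx 0.07$). The calibration is exposed, reproducible and
overridable; the severity subgroups never use it (they run degenerate
all-moderate or all-severe mixes).

### The life-table stub

Remaining life expectancy and background mortality come from a bundled
Gompertz life table (`generate_life_table()`), scaled so that remaining
life expectancy at age 40 is 28 years with hazard slope 0.09 per year of
age — values plausible for Sierra Leonean males. It is self-consistent
(the `ex` column is recomputable from `q` within half a year) and
clearly non-authoritative: substitute a real national table (CSV with
`age,q,ex`) for applied work.

## Costs

Per-procedure costs (2023 USD: AC 149, MD 163) are treated as
all-inclusive; the four post-operative complication categories
(excessive pain, impaired wound healing, wound infection,
hematoma/reoperation) retain their trial rates with unit costs
defaulting to zero, so users with their own bottom-up line items can
re-enable the complication component. `bottom_up_cost()` implements the
standard costing split: consumables per procedure, annualized
capital/overhead/staff spread over the annual procedure volume by
allocation share. Re-repairs use the same provider and cost as the
initial repair. Under the defaults the model arrives at discounted
10-year totals of about 164 (AC) and 252 (MD) USD per patient — the
procedure plus roughly 15 and 89 USD of discounted re-repair outlays
respectively.

## Cost-effectiveness analysis

`hernia_cea()` compares each provider against no treatment and AC
against MD, in the base case and in moderate and severe pre-operative
pain subgroups. The ICER is incremental cost over DALYs averted;
dominance (cheaper *and* more effective) is reported instead of a
ratio. Thresholds follow WHO practice: very cost-effective below one GDP
per capita (USD 476 for 2022), cost-effective below three times that
(USD 1,428 per DALY averted), with boundary values assigned to the less
favourable class. The source abstract quotes USD 1,427 as "the GDP per
capita"; the methods section's 476 and $3\times476=1428$ are used here
and the abstract figure is treated as a rounding of the willingness-to-pay
threshold.

## Sensitivity analyses

**Deterministic (tornado).** `one_way_dsa()` re-runs the full analysis
with one parameter at a time at its low/high bound (the published grid:
discount rate 0–3.5%, starting age 30–50, and ±20% style ranges on
costs, disability weights and risks) and ranks parameters by ICER span.
Switching the half-cycle correction off is a boolean setting rather than
a scalar path and is probed directly through `settings`.

**Probabilistic.** `run_psa()` redraws disability weights and the
recurrence/contralateral risks per simulation — beta distributions
matched to the published means and standard deviations by the method of
moments, with a truncated-normal fallback where the moments are
infeasible for a beta — and re-evaluates the whole model per draw
(default 1,000 simulations, fixed seed recorded in all outputs).
Procedure costs are not varied, mirroring the published PSA input block,
so cost uncertainty enters only through recurrence. Distribution
families are a design decision; the published per-parameter illustrative
draws are not constraints. `ceac()` uses net monetary benefit
($\lambda \Delta E - \Delta C \ge 0$) for acceptability-curve
membership, avoiding ICER sign ambiguity, and `ceac_crossings()` reports
both the 50% and the 100% probability thresholds since either reading of
"becomes cost-effective at" is defensible.

## Budget impact

The national projection (2024–2033, undiscounted by design) starts from
a prevalent pool of 220,748 untreated men (8.6% prevalence; the implied
adult-male population of 2,566,837 is back-derived from those two
published figures) growing at 2.1%/year — a plausible national growth
rate, calibrated so the decade's total backlog (initial pool plus
accumulated incidence at 1,250 per 100,000) is approximately 578,000.
Incidence and repair rates are interpreted per 100,000 adult males, the
prevalence base. The open-budget scenario spreads the repairs needed to
clear that backlog evenly over the ten years; the workforce is sized
from repairs per provider-year — 27.5, solved from the published
requirement that about 2,100 newly trained providers clear the backlog
in a decade, and flagged as calibrated — with USD 2,000 training per
provider and USD 12,000 renovation per facility of three providers.
Capped scenarios fund repairs at the share-weighted operation cost
(68% MD / 32% AC ≈ USD 158.5) plus a proportional training/renovation
overhead (≈ USD 21.8 per repair) until the ceiling is exhausted. The
per-repair operation cost includes a complication-treatment component of
USD 3.70, set so that removing it lowers the open-budget total by about
2%, consistent with the published budget sensitivity; `bia_sensitivity()`
also varies each cost input ±20%, facility staffing between 2 and 4
providers, and productivity up to five repairs per day (1,300 per
provider-year on a 5-day, 52-week elective schedule).

## Validation and the synthetic-data machinery

Two independent routes cross-check the cohort engine:

* `microsim_oracle()` pushes individual patients through the identical
  state logic with per-individual random transitions; its means converge
  to the cohort totals, and the test suite requires agreement within
  three Monte-Carlo standard errors at $n = 100{,}000$.
* `generate_trial_cohort()` / `estimate_parameters()` emulate the source
  trial at the individual level (pre/post IPQ bands, one-year recurrence,
  independent Bernoulli complications — no joint structure is reported,
  so none is imposed) and close a parameter-recovery loop within exact
  binomial confidence intervals at $n = 50{,}000$.

What the synthetic data do *not* emulate: trial logistics (randomization
blocks, loss to follow-up), correlation between complications and
recurrence, age structure within the cohort, and any real post-operative
chronic-pain distribution. Passing these checks therefore demonstrates
internal consistency of the engine and estimators, not fidelity to any
patient population.

## Numerical choices and problem sizes

Accruals use full double precision throughout; printed reports round to
the conventions of the field (whole USD, two-decimal DALYs). Occupancy
conservation is enforced to $10^{-9}$ per cycle and transition rows to
$10^{-12}$. Degenerate inputs are rejected at validation (probabilities
outside $[0,1]$, non-monotone disability weights, pain mixes not summing
to one, life tables not covering the modelled ages, zero-hazard life
tables whose expectancy would be unbounded). The test suite runs the
microsimulation oracle at $n = 100{,}000$ and the probabilistic
sensitivity analysis at 400 draws; both sizes give Monte-Carlo errors
comfortably below the tolerances they are tested against, and the full
published size (1,000 draws) runs in seconds via `write_psa_report()`.

## Known limitations

* The four-state structure has no memory: recurrence risk does not vary
  with age, time since repair, or number of prior repairs.
* DALYs rest solely on reported pain; other morbidity dimensions of
  hernia disease are not captured.
* The life-table stub and the calibrated pain mix are stand-ins for
  unpublished inputs; headline reproductions inherit that uncertainty,
  which is why the shipped defaults are documented as calibration
  artifacts and are trivially replaceable.
* Costs take the healthcare-system perspective only; out-of-pocket and
  productivity costs are out of scope, as is currency conversion (all
  inputs are consumed already in 2023 USD).

## A worked base case

```{r base-case}
params <- default_parameters()
cea <- hernia_cea(params)
cea$base$ac_vs_none
cea$base$ac_vs_md

open <- open_budget_scenario(params$budget_impact)
print(open)
```
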