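Package: herniaCEA
Title: Cost-Effectiveness and Budget Impact of Task-Shared Inguinal
    Hernia Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov cohort model for the economic evaluation of elective
    open mesh inguinal hernia repair delivered through surgical
    task-sharing by associate clinicians and non-specialist medical
    doctors, as practised in Sierra Leone.  Simulates a four-state
    annual-cycle cohort (new hernia, recurrent hernia, repaired, dead)
    with background and premature hernia mortality, computes discounted
    costs and disability-adjusted life years (YLD + YLL) from Inguinal
    Pain Questionnaire derived disability weights, and reports
    incremental cost-effectiveness ratios with dominance and
    willingness-to-pay classification.  Includes one-way deterministic
    sensitivity analysis (tornado), probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves, a national
    budget-impact projection of surgical backlog clearance under open
    and capped budgets, an individual-level microsimulation oracle, and
    a synthetic trial-cohort generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
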