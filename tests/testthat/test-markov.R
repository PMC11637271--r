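test_that("discount factors follow the timing conventions", {
  expect_equal(discount_factor(5, 0, "end"), 1)
  expect_equal(discount_factor(1, 0.03, "end"), 1 / 1.03)
  expect_equal(discount_factor(1, 0.03, "start"), 1)
  expect_equal(discount_factor(1, 0.03, "mid"), 1.03^-0.5)
  expect_equal(sum(discount_factor(1:10, 0.03, "end")), ANNUITY_10Y_3PC,
               tolerance = 1e-9)
  expect_error(discount_factor(1, 0.03, "quarterly"), "timing")
})

test_that("transition matrices carry the configured risks and are stochastic", {
  p <- base_params()
  lt0 <- no_death_params()$life_table

  # untreated with premature death only: new-hernia -> dead entry
  M <- build_transition_matrix(p$strategies$none, 40, lt0,
                               p_premature_death = 0.0011)
  expect_equal(M["new_hernia", "dead"], 0.0011)
  expect_equal(M["recurrent_hernia", "dead"], 0.0011)

  # AC strategy at zero background mortality: repaired -> recurrent
  M <- build_transition_matrix(p$strategies$ac, 40, lt0)
  expect_equal(M["repaired", "recurrent_hernia"], 0.0092)
  expect_equal(M["repaired", "new_hernia"], (1 - 0.0092) * 0.0038)

  # all risks zero: identity on living states
  none0 <- strategy_params("NONE", 0, 0, 0)
  M <- build_transition_matrix(none0, 40, lt0, treated = FALSE)
  expect_equal(unname(diag(M)), rep(1, 4))

  # row-stochastic at realistic mortality, across ages
  for (age in c(40, 45, 49)) {
    M <- build_transition_matrix(p$strategies$md, age, p$life_table)
    expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["dead", ]), c(0, 0, 0, 1))  # absorbing
  }
  expect_error(build_transition_matrix(p$strategies$ac, 150, p$life_table),
               "cover")
})

test_that("cohort occupancy is conserved and death is absorbing", {
  p <- base_params()
  for (id in c("none", "ac", "md")) {
    occ <- attr(run_cohort(p, id), "occupancy")
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(occ[, "dead"]) >= 0))
    expect_true(all(occ >= 0))
  }
})

test_that("a riskless untreated cohort never leaves the new-hernia state", {
  p <- no_death_params()
  occ <- attr(run_cohort(p, "none"), "occupancy")
  expect_equal(unname(occ[, "new_hernia"]), rep(1, 11))
})

test_that("zero discount without correction: discounted equals undiscounted", {
  p <- base_params()
  p$settings$discount_rate <- 0
  p$settings$half_cycle_correction <- FALSE
  p <- validate_parameters(unclass(p))
  tr <- run_cohort(p, "md")
  expect_equal(tr$cost_disc, tr$cost_undisc)
  expect_equal(tr$yld_disc, tr$yld_undisc)
  expect_equal(tr$yll_disc, tr$yll_undisc)
})

test_that("half-cycle correction values a surviving annuity at 8.658", {
  # fully surviving severe cohort: state time should equal the average of
  # start- and end-of-cycle discounted annuities
  p <- no_death_params()
  tr <- run_cohort(p, "none", pain_pre = pure_mix("severe"))
  expect_equal(sum(tr$yld_disc), 0.3240 * ANNUITY_10Y_3PC_HCC,
               tolerance = 1e-7)
})

test_that("apply_half_cycle_correction halves a one-cycle transient", {
  # treated cohort with no risks at discount 0: the single pre-operative
  # cycle decays 1 -> 0, so the trapezoid values it at half a cycle
  p <- no_death_params()
  p$settings$discount_rate <- 0
  p$settings$half_cycle_correction <- FALSE
  p$strategies$ac$p_recurrence <- 0
  p$strategies$ac$p_contralateral <- 0
  p <- validate_parameters(unclass(p))
  tr <- run_cohort(p, "ac", pain_pre = pure_mix("severe"))
  expect_equal(sum(tr$yld_undisc), 0.3240)  # one full cycle at cycle-start
  trc <- apply_half_cycle_correction(tr)
  expect_equal(sum(trc$yld_disc), 0.3240 * 0.5)
  # constant occupancy is unchanged by the correction at rate 0
  tr_none <- run_cohort(p, "none", pain_pre = pure_mix("severe"))
  expect_equal(sum(apply_half_cycle_correction(tr_none)$yld_disc),
               sum(tr_none$yld_disc))
})

test_that("trace export writes one row per cycle", {
  tr <- run_cohort(base_params(), "ac")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 10)
  expect_true(all(c("cycle", "age", "repaired", "cost_disc") %in% names(df)))
})
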