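test_that("untreated single-band YLD matches the closed-form annuity", {
  p <- no_death_params()
  tr_sev <- run_cohort(p, "none", pain_pre = pure_mix("severe"))
  expect_equal(compute_yld(tr_sev), 0.3240 * ANNUITY_10Y_3PC_HCC,
               tolerance = 1e-7)
  tr_mod <- run_cohort(p, "none", pain_pre = pure_mix("moderate"))
  expect_equal(compute_yld(tr_mod), 0.1140 * ANNUITY_10Y_3PC_HCC,
               tolerance = 1e-7)

  # zero weights give zero YLD
  dw0 <- c(none = 0, mild = 0, moderate = 0, severe = 0)
  expect_equal(compute_yld(tr_sev, dws = dw0), 0)
})

test_that("with discount 0 and no deaths YLD equals DW x horizon exactly", {
  p <- no_death_params()
  p$settings$discount_rate <- 0
  p$settings$half_cycle_correction <- FALSE
  p <- validate_parameters(unclass(p))
  tr <- run_cohort(p, "none", pain_pre = pure_mix("moderate"))
  expect_equal(compute_yld(tr), 0.1140 * 10)
})

test_that("YLD is linear in each disability weight", {
  p <- no_death_params()
  tr <- run_cohort(p, "none", pain_pre = pure_mix("severe"))
  dw2 <- base_params()$disability_weights
  dw2["severe"] <- 2 * dw2["severe"]
  expect_equal(compute_yld(tr, dws = dw2), 2 * compute_yld(tr),
               tolerance = 1e-12)
})

test_that("YLL vanishes without premature death and is nearly linear in it", {
  p <- base_params()
  tr <- run_cohort(p, "ac")
  expect_equal(compute_yll(tr), 0)          # treated: no premature deaths
  p0 <- p; p0$premature_death$p_complication <- 0
  p0 <- validate_parameters(unclass(p0))
  expect_equal(compute_yll(run_cohort(p0, "none")), 0)

  # near-linearity for small probabilities: scaling p by 5 scales YLL by
  # 5 within 1%
  p1 <- p; p1$premature_death$p_complication <- 0.002
  p5 <- p; p5$premature_death$p_complication <- 0.010
  y1 <- compute_yll(run_cohort(validate_parameters(unclass(p1)), "none"))
  y5 <- compute_yll(run_cohort(validate_parameters(unclass(p5)), "none"))
  expect_true(y1 > 0)
  expect_equal(y5 / y1, 5, tolerance = 0.01)
})

test_that("a full premature death at known life expectancy is valued as its annuity", {
  # one cycle, certain premature death, zero discount, full-LE convention
  p <- base_params()
  p$settings$horizon <- 1L
  p$settings$discount_rate <- 0
  p$premature_death$p_complication <- 1
  p$premature_death$p_mortality_given_complication <- 1
  ages <- 18:100
  p$life_table <- data.frame(age = ages, q = 0, ex = 69 - ages)  # ex(41)=28
  p <- validate_parameters(unclass(p))
  tr <- run_cohort(p, "none")
  expect_equal(compute_yll(tr), 28)

  p$settings$yll_convention <- "horizon_capped"
  p <- validate_parameters(unclass(p))
  tr <- run_cohort(p, "none")
  expect_equal(compute_yll(tr), 0)  # death at the horizon loses no modelled years
})

test_that("the horizon-capped convention yields less YLL than full remaining LE", {
  p <- base_params()
  pc <- p; pc$settings$yll_convention <- "horizon_capped"
  pc <- validate_parameters(unclass(pc))
  expect_lt(compute_yll(run_cohort(pc, "none")),
            compute_yll(run_cohort(p, "none")))
})

test_that("DALY decomposes exactly into YLD plus YLL", {
  for (id in c("none", "ac", "md")) {
    d <- daly_result(run_cohort(base_params(), id))
    expect_equal(d$daly, d$yld + d$yll, tolerance = 1e-12)
    expect_true(d$yld >= 0 && d$yll >= 0)
  }
  expect_equal(dalys_averted(0.75, 0.09), 0.66)
  expect_equal(dalys_averted(1.3, 1.3), 0)
})

test_that("the literal life-expectancy YLD formulation is available for comparison", {
  tr <- run_cohort(base_params(), "none")
  lit <- compute_yld(tr, method = "life_expectancy")
  dw_pre <- sum(base_params()$pain_pre * base_params()$disability_weights)
  expect_equal(lit, dw_pre * lt_ex(base_params()$life_table, 40))
  expect_gt(lit, compute_yld(tr))  # full-LE valuation exceeds 10-year accrual
})
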