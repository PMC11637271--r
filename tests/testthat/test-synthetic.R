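test_that("synthetic cohorts hit the configured rates and are reproducible", {
  p <- base_params()
  co <- generate_trial_cohort(10000, provider_mix = 1, seed = 21)
  expect_true(all(co$provider == "AC"))
  f <- mean(co$recurrence_within_1y)
  se <- sqrt(0.0092 * (1 - 0.0092) / 10000)
  expect_lt(abs(f - 0.0092), 3 * se)

  co2 <- generate_trial_cohort(500, seed = 8)
  co3 <- generate_trial_cohort(500, seed = 8)
  expect_identical(co2, co3)
  expect_false(identical(co2, generate_trial_cohort(500, seed = 9)))
})

test_that("degenerate pain mixes pin the sampled IPQ scores", {
  sev <- generate_trial_cohort(
    200, pain = list(pre = pure_mix("severe"), post = pure_mix("none")),
    seed = 2)
  expect_true(all(sev$pre_op_ipq %in% 6:7))
  expect_true(all(sev$post_op_ipq == 1))
})

test_that("the generator/estimator round trip recovers the true rates", {
  p <- base_params()
  co <- generate_trial_cohort(50000, provider_mix = 0.5, seed = 31)
  est <- estimate_parameters(co)
  # recurrence within its 95% binomial CI per provider
  expect_true(est$ac$p_recurrence["lower"] <= 0.0092 &&
                0.0092 <= est$ac$p_recurrence["upper"])
  expect_true(est$md$p_recurrence["lower"] <= 0.0686 &&
                0.0686 <= est$md$p_recurrence["upper"])
  # complication rates likewise
  for (cm in c("excessive_pain", "wound_infection")) {
    truth <- p$strategies$ac$complication_rates[[cm]]
    expect_true(est$ac$complication_rates["lower", cm] <= truth &&
                  truth <= est$ac$complication_rates["upper", cm])
  }
  # pain-band fractions close to the configured mix
  expect_equal(unname(est$pain_pre), unname(p$pain_pre), tolerance = 0.02)

  all_rec <- generate_trial_cohort(100, seed = 4)
  all_rec$recurrence_within_1y <- TRUE
  expect_equal(unname(estimate_parameters(all_rec)$ac$p_recurrence["estimate"]),
               1)
  only_ac <- co[co$provider == "AC", ]
  expect_error(estimate_parameters(only_ac), "MD")
})

test_that("per-provider estimates are independent of the other stratum", {
  co <- generate_trial_cohort(20000, provider_mix = 0.5, seed = 13)
  est_full <- estimate_parameters(co)
  co_ac_only <- co
  co_ac_only$recurrence_within_1y[co_ac_only$provider == "MD"] <- TRUE
  est_mod <- estimate_parameters(co_ac_only)
  expect_equal(est_mod$ac$p_recurrence, est_full$ac$p_recurrence)
})

test_that("microsimulation limits: riskless strategy and closed-form DALYs", {
  # zero-risk treated strategy with no disability: cost is the procedure
  # cost exactly, DALYs zero
  p <- no_death_params()
  p$strategies$ac$p_recurrence <- 0
  p$strategies$ac$p_contralateral <- 0
  p$pain_pre <- pure_mix("none")
  p <- validate_parameters(unclass(p))
  ms <- microsim_oracle(p, "ac", n = 500, seed = 6)
  expect_equal(ms$mean_cost, 149)
  expect_equal(ms$se_cost, 0)
  expect_equal(ms$mean_daly, 0)

  # untreated severe cohort, no deaths, discount 0, no correction:
  # every individual accrues DW x horizon exactly
  p2 <- no_death_params()
  p2$settings$discount_rate <- 0
  p2$settings$half_cycle_correction <- FALSE
  p2$pain_pre <- pure_mix("severe")
  p2 <- validate_parameters(unclass(p2))
  ms2 <- microsim_oracle(p2, "none", n = 200, seed = 6)
  expect_equal(ms2$mean_daly, 0.3240 * 10, tolerance = 1e-12)
})

test_that("microsimulation agrees with the cohort engine within Monte-Carlo error", {
  p <- base_params()
  for (id in c("ac", "md")) {
    co <- run_strategy(p, id)
    ms <- microsim_oracle(p, id, n = 20000, seed = 17)
    expect_lt(abs(ms$mean_cost - co$cost$total_disc), 3 * ms$se_cost)
    expect_lt(abs(ms$mean_daly - co$daly$daly), 3 * ms$se_daly)
  }
})
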