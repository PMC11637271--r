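test_that("bottom-up costing splits consumables from annualized shared items", {
  expect_equal(bottom_up_cost(data.frame(), 100), 0)
  one <- data.frame(name = "suture", category = "materials", quantity = 2,
                    unit_cost = 10, allocation_share = 1)
  expect_equal(bottom_up_cost(one, 1000), 20)

  items <- rbind(
    one,
    data.frame(name = "theatre", category = "capital", quantity = 1,
               unit_cost = 50000, allocation_share = 0.5),
    data.frame(name = "utilities", category = "overhead", quantity = 1,
               unit_cost = 10000, allocation_share = 0.5))
  expect_equal(bottom_up_cost(items, 500), 20 + (25000 + 5000) / 500)
  expect_error(bottom_up_cost(items, 0), "positive")
})

test_that("a calibrated fixture item set reproduces the per-procedure costs", {
  # calibration artifacts, not supplementary line items: consumables plus
  # a provider-time block spread over an annual theatre volume
  fixture <- function(hr_cost) rbind(
    data.frame(name = "mesh_kit", category = "materials", quantity = 1,
               unit_cost = 52, allocation_share = 1),
    data.frame(name = "medicines", category = "medicines", quantity = 1,
               unit_cost = 27, allocation_share = 1),
    data.frame(name = "provider_time", category = "human_resources",
               quantity = 1, unit_cost = hr_cost, allocation_share = 1),
    data.frame(name = "theatre_overhead", category = "overhead",
               quantity = 1, unit_cost = 26000, allocation_share = 0.5))
  expect_equal(bottom_up_cost(fixture(57000), 1000), 149)
  expect_equal(bottom_up_cost(fixture(71000), 1000), 163)
})

test_that("expected complication cost is a rate-weighted sum, linear in rates", {
  p <- base_params()
  expect_equal(expected_complication_cost(p$strategies$ac), 0)  # unit costs 0

  ac <- p$strategies$ac
  ac$complication_unit_costs <- c(excessive_pain = 10,
                                  impaired_wound_healing = 20,
                                  wound_infection = 30,
                                  hematoma_reoperation = 163)
  expect_equal(expected_complication_cost(ac),
               0.0522 * 10 + 0.0696 * 20 + 0.0522 * 30 + 0.0174 * 163)
  ac2 <- ac
  ac2$complication_rates <- ac$complication_rates / 2
  expect_equal(expected_complication_cost(ac2),
               expected_complication_cost(ac) / 2)
})

test_that("cohort costs decompose and respect no-treatment and no-recurrence limits", {
  p <- base_params()
  expect_equal(cohort_cost(run_cohort(p, "none"))$total_disc, 0)

  p0 <- p
  p0$strategies$ac$p_recurrence <- 0
  p0$strategies$ac$p_contralateral <- 0
  p0 <- validate_parameters(unclass(p0))
  c0 <- cohort_cost(run_cohort(p0, "ac"))
  expect_equal(c0$total_disc, 149)  # initial procedure only
  expect_equal(c0$re_repair_disc, 0)

  ca <- cohort_cost(run_cohort(p, "ac"))
  expect_equal(ca$total_disc, ca$initial + ca$re_repair_disc,
               tolerance = 1e-9)
  expect_gt(ca$re_repair_disc, 0)
})

test_that("cohort cost is monotone in recurrence risk and procedure cost", {
  p <- base_params()
  total_at <- function(p_rec, unit) {
    q <- p
    q$strategies$ac$p_recurrence <- p_rec
    q$strategies$ac$cost_per_procedure <- unit
    q <- validate_parameters(unclass(q))
    cohort_cost(run_cohort(q, "ac"))$total_disc
  }
  tot <- vapply(seq(0, 0.2, by = 0.05), total_at, numeric(1), unit = 149)
  expect_true(all(diff(tot) > 0))
  tot <- vapply(c(100, 149, 200), total_at, numeric(1), p_rec = 0.0092)
  expect_true(all(diff(tot) > 0))
})

test_that("AC total cost is below MD total cost under defaults", {
  p <- base_params()
  expect_lt(cohort_cost(run_cohort(p, "ac"))$total_disc,
            cohort_cost(run_cohort(p, "md"))$total_disc)
})
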