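test_that("parameter paths resolve and update scalars", {
  p <- base_params()
  expect_equal(get_param(p, "strategies$ac$cost_per_procedure"), 149)
  expect_equal(get_param(p, "disability_weights$moderate"), 0.114)
  p2 <- set_param(p, "strategies$ac$cost_per_procedure", 179)
  expect_equal(p2$strategies$ac$cost_per_procedure, 179)
  expect_equal(p$strategies$ac$cost_per_procedure, 149)  # copy semantics
  expect_error(get_param(p, "strategies$ac$nonexistent"), "resolve")
})

test_that("one-way DSA spans behave: zero-width specs, linearity, ordering invariance", {
  p <- base_params()
  specs <- default_dsa_specs(p)

  flat <- specs[1, ]
  flat$low <- flat$base; flat$high <- flat$base
  d0 <- one_way_dsa(p, flat)
  expect_equal(d0$span, 0, tolerance = 1e-12)

  # ICER numerator is linear in the AC procedure cost
  cost_spec <- specs[specs$parameter == "strategies$ac$cost_per_procedure", ]
  d <- one_way_dsa(p, cost_spec)
  base_icer <- attr(d, "base_icer")
  expect_equal(d$icer_high, base_icer * 179 / 149, tolerance = 1e-9)
  expect_equal(d$icer_low, base_icer * 120 / 149, tolerance = 1e-9)

  # spans invariant to spec ordering
  d_fwd <- one_way_dsa(p, specs)
  d_rev <- one_way_dsa(p, specs[rev(seq_len(nrow(specs))), ])
  expect_equal(d_fwd$span[order(d_fwd$parameter)],
               d_rev$span[order(d_rev$parameter)], tolerance = 1e-12)
  # sorted by descending span
  expect_true(all(diff(d_fwd$span) <= 1e-12))
  expect_error(one_way_dsa(p, transform(specs, low = base + 1)), "low <= base")
})

test_that("PSA sampling matches requested moments and is reproducible", {
  dists <- default_psa_dists()
  d1 <- sample_psa(dists, 1000, seed = 11)
  d2 <- sample_psa(dists, 1000, seed = 11)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 1000)

  # beta method-of-moments recovers mean and sd of the moderate DW
  x <- d1[, "disability_weights$moderate"]
  expect_lt(abs(mean(x) - 0.1140), 3 * 0.0200 / sqrt(1000))
  expect_lt(abs(stats::sd(x) - 0.0200), 0.15 * 0.0200)
  expect_true(all(d1 >= 0 & d1 <= 1))

  # degenerate sd reproduces the mean
  d0 <- sample_psa(data.frame(parameter = "disability_weights$mild",
                              mean = 0.011, sd = 0, family = "beta"),
                   50, seed = 1)
  expect_equal(unname(d0[, 1]), rep(0.011, 50))

  # infeasible beta falls back to truncated normal with a warning
  expect_warning(
    sample_psa(data.frame(parameter = "x", mean = 0.5, sd = 0.6,
                          family = "beta"), 10, seed = 1),
    "truncated")
})

test_that("a degenerate PSA reproduces the deterministic increments", {
  p <- base_params()
  dists <- default_psa_dists()
  dists$sd <- 0
  dists$mean <- c(0.0110, 0.1140, 0.3240, 0.0092, 0.0686, 0.0038)
  psa <- run_psa(p, dists, n = 1, seed = 3)
  expect_equal(psa$increments[["ac_vs_none.d_cost"]],
               unname(psa$deterministic["d_cost", "ac_vs_none"]),
               tolerance = 1e-9)
  expect_equal(psa$increments[["ac_vs_none.d_daly"]],
               unname(psa$deterministic["d_daly", "ac_vs_none"]),
               tolerance = 1e-9)
})

test_that("CEAC limits and monotonicity hold, and crossings are reported", {
  p <- base_params()
  psa <- run_psa(p, n = 60, seed = 5)
  curve <- ceac(psa, thresholds = seq(0, 1500, by = 25))
  # at zero threshold repair is never cost-effective vs none (it costs more)
  expect_equal(curve$ac_vs_none[curve$threshold == 0], 0)
  # at a high threshold every draw averts DALYs, so probability is 1
  expect_equal(max(curve$ac_vs_none), 1)
  # monotone non-decreasing when all draws avert DALYs
  expect_true(all(psa$increments[["ac_vs_none.d_daly"]] > 0))
  expect_true(all(diff(curve$ac_vs_none) >= 0))
  # AC dominating MD: cost-effective already at threshold zero
  expect_equal(curve$ac_vs_md[curve$threshold == 0], 1)

  cr <- ceac_crossings(curve)
  expect_true(cr$at_100pct[cr$comparison == "ac_vs_none"] <=
                cr$at_100pct[cr$comparison == "md_vs_none"])
})
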