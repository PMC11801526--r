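test_that("annual-to-cycle conversion follows the constant-hazard form", {
  expect_equal(annual_prob_to_cycle(0, 0.25), 0)
  expect_equal(annual_prob_to_cycle(1, 0.25), 1)
  expect_equal(annual_prob_to_cycle(0.06, 0.25), 0.015350, tolerance = 1e-4)
  # composing four quarterly cycles recovers the annual probability
  for (p in c(0.01, 0.06, 0.10, 0.5, 0.99)) {
    q <- annual_prob_to_cycle(p, 0.25)
    expect_equal(1 - (1 - q)^4, p)
  }
  expect_error(annual_prob_to_cycle(1.2, 0.25), "\\[0, 1\\]")
})

test_that("transition matrix composes relapse, remission and mortality", {
  cfg <- table1_default_config()
  P <- build_transition_matrix(cfg)
  # frozen from independent arithmetic: death applied first, survivors
  # split by per-cycle relapse/remission
  expect_equal(unname(P["improved", ]),
               c(0.983540572, 0.015332525, 0.001126903), tolerance = 1e-8)
  expect_equal(unname(P["not_improved", ]),
               c(0.025957824, 0.972563901, 0.001478275), tolerance = 1e-8)
  expect_equal(unname(P["dead", ]), c(0, 0, 1))
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)

  cfg0 <- cfg
  for (nm in c("relapse_annual", "remission_annual",
               "mortality_improved_annual", "mortality_not_improved_annual"))
    cfg0 <- set_shared(cfg0, nm, 0)
  expect_equal(unname(build_transition_matrix(cfg0)), diag(3))

  cfg1 <- set_shared(cfg0, "remission_annual", 1)
  expect_equal(unname(build_transition_matrix(cfg1)["not_improved", ]),
               c(1, 0, 0))
})

test_that("discounting is stepwise annual from the policy start cycle", {
  pol <- policy_settings()
  expect_equal(discount_factor(1:4, pol), rep(1, 4))
  expect_equal(discount_factor(5, pol), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(8, pol), 1 / 1.03)
  expect_equal(discount_factor(9, pol), 1 / 1.03^2)
  expect_equal(discount_factor(20, pol), 0.888487, tolerance = 1e-6)
  df <- discount_factor(1:20, pol)
  expect_true(all(diff(df) <= 0))
  expect_error(discount_factor(21, pol), "out of range")
  # per-cycle compounding agrees at year boundaries
  expect_equal(discount_factor(20, pol, "per-cycle"), 1 / 1.03^4)
})

test_that("degenerate cohorts hit closed-form totals", {
  # full health, no deaths, no discounting: exactly 5 life-years
  cfg <- clean_config()
  cfg <- set_shared(cfg, "utility_improved", 1)
  cfg <- set_shared(cfg, "utility_not_improved", 1)
  res <- run_cohort("TM", cfg)
  expect_equal(res$total_qalys, 5)

  # absorbing response: occupancy never leaves the improved state
  cfg2 <- clean_config()
  cfg2 <- set_shared(cfg2, "relapse_annual", 0)
  cfg2$arms$TM$p_respond$base <- 1 - 1e-9  # must stay in (0, 1)
  cfg2$arms$TM$p_respond$low <- NA_real_
  cfg2$arms$TM$p_respond$high <- NA_real_
  cfg2$arms$TM$p_respond$distribution <- "fixed"
  res2 <- run_cohort("TM", cfg2)
  expect_equal(res2$trace$improved, rep(1 - 1e-9, 20))

  # one-cycle horizon, no discount: hand-computable expectation
  cfg3 <- clean_config()
  cfg3$policy$n_cycles <- 1L
  cfg3$policy$discount_start_cycle <- 1L  # moot: rate is zero
  res3 <- run_cohort("TM", cfg3)
  expect_equal(res3$total_qalys, (0.61 * 0.63 + 0.39 * 0.54) * 0.25)
  expect_equal(res3$total_qalys, 0.148725)
})

test_that("traces conserve occupancy and the dead state is monotone", {
  cfg <- table1_default_config()
  for (arm in names(cfg$arms)) {
    tr <- run_cohort(arm, cfg)$trace
    expect_equal(tr$improved + tr$not_improved + tr$dead, rep(1, 20),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= 0))
    expect_true(all(tr$cost >= 0) && all(tr$qaly >= 0))
  }
  # with zero mortality nobody ever dies
  cfg0 <- clean_config()
  expect_equal(run_cohort("HE", cfg0)$trace$dead, rep(0, 20))
})

test_that("zero discount rate equates discounted and undiscounted totals", {
  cfg <- table1_default_config()
  cfg$policy$annual_discount_rate <- 0
  r <- run_cohort("PE", cfg)
  expect_equal(r$total_qalys, r$total_qalys_undiscounted)
  expect_equal(r$total_cost, r$total_cost_undiscounted)
})

test_that("QALYs respond monotonically to utility and response inputs", {
  cfg <- table1_default_config()
  base <- run_cohort("TM", cfg)
  up <- set_shared(cfg, "utility_improved", 0.70)
  expect_gt(run_cohort("TM", up)$total_qalys, base$total_qalys)

  cfg_hi <- cfg
  cfg_hi$arms$TM$p_respond$base <- 0.70
  hi <- run_cohort("TM", cfg_hi)
  expect_gt(hi$total_qalys, base$total_qalys)
  expect_lt(hi$healthcare_cost, base$healthcare_cost)
})

test_that("trace exports as a per-cycle CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(run_cohort("HE", table1_default_config()), f)
  back <- read.csv(f)
  expect_equal(nrow(back), 20)
  expect_named(back, c("cycle", "improved", "not_improved", "dead",
                       "discount", "cost", "cost_discounted",
                       "qaly", "qaly_discounted"))
})
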