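test_that("tornado ranks utilities on top and keeps NMB positive for TM vs PE", {
  cfg <- table1_default_config()
  tor <- suppressWarnings(one_way_tornado(cfg, c("TM", "PE")))
  # 12 parameters carry ranges (3 response, 3 intervention costs,
  # 2 mortality, 2 health-care costs, 2 utilities)
  expect_equal(nrow(tor), 12)
  expect_true(all(diff(tor$bar_width) <= 0))
  expect_setequal(tor$parameter[1:2],
                  c("utility_improved", "utility_not_improved"))
  expect_true(all(pmin(tor$nmb_at_low, tor$nmb_at_high) > 0))
  # parameters that do not touch the TM/PE pair have zero-width bars
  expect_equal(tor$bar_width[tor$parameter == "p_respond_HE"], 0)
})

test_that("tornado skips rangeless parameters with a warning and honours degenerate ranges", {
  cfg <- table1_default_config()
  expect_warning(one_way_tornado(cfg, c("TM", "PE")), "relapse_annual")
  cfg$shared$utility_improved$low <- 0.63
  cfg$shared$utility_improved$high <- 0.63
  tor <- suppressWarnings(one_way_tornado(cfg, c("TM", "PE")))
  expect_equal(tor$bar_width[tor$parameter == "utility_improved"], 0)
})

test_that("moment-matched samplers hit their target mean and sd", {
  set.seed(101)
  n <- 1e6
  cases <- list(
    list(spec = parameter_spec("tm_resp", 0.61, 0.490, 0.730, "beta",
                               "probability"),
         mean = 0.61, sd = (0.730 - 0.490) / 3.92),
    list(spec = parameter_spec("hc_ni", 12154, 9723, 14585, "gamma",
                               "cost_annual"),
         mean = 12154, sd = (14585 - 9723) / 3.92)
  )
  for (cs in cases) {
    x <- fit_sampler(cs$spec)$draw(n)
    expect_equal(mean(x), cs$mean, tolerance = 0.005)
    expect_equal(sd(x), cs$sd, tolerance = 0.02)
  }
  # triangular: hard bounds, mean (low + mode + high) / 3
  tri <- fit_sampler(parameter_spec("pe_cost", 2822, 1605, 3386,
                                    "triangular", "cost_one_time"))
  x <- tri$draw(n)
  expect_true(all(x >= 1605 & x <= 3386))
  expect_equal(mean(x), (1605 + 2822 + 3386) / 3, tolerance = 0.005)
  # fixed: a point mass
  fx <- fit_sampler(parameter_spec("relapse_annual", 0.06, role = "annual_rate"))
  expect_equal(fx$draw(5), rep(0.06, 5))
  # beta demands a mean strictly inside the unit interval
  expect_error(fit_sampler(parameter_spec("bad", 1.0, 0.9, 1.1, "beta",
                                          "cost_annual")),
               "\\(0, 1\\)")
})

test_that("PSA is seed-reproducible and degenerates to the base case", {
  cfg <- table1_default_config()
  p1 <- run_psa(cfg, n_draws = 50, seed = 7)
  p2 <- run_psa(cfg, n_draws = 50, seed = 7)
  expect_identical(p1$arms, p2$arms)
  expect_identical(p1$optimal, p2$optimal)

  fixed <- run_psa(all_fixed_config(), n_draws = 5, seed = 7)
  base <- run_model(all_fixed_config())
  for (a in names(base)) {
    expect_identical(fixed$arms[[a]]$cost,
                     rep(base[[a]]$total_cost, 5))
    expect_identical(fixed$arms[[a]]$qalys,
                     rep(base[[a]]$total_qalys, 5))
  }
  expect_error(run_psa(cfg, n_draws = 0), ">= 1")
})

test_that("PSA tallies agree across seeds within binomial bounds", {
  cfg <- table1_default_config()
  t1 <- run_psa(cfg, 400, seed = 11)$tallies$TM_vs_PE
  t2 <- run_psa(cfg, 400, seed = 12)$tallies$TM_vs_PE
  # 99% binomial bound on the difference of two proportions at n = 400
  for (f in c("dominant", "optimal")) {
    p <- (t1[[f]] + t2[[f]]) / 2
    bound <- 2.58 * sqrt(2 * p * (1 - p) / 400)
    expect_lt(abs(t1[[f]] - t2[[f]]), bound + 1e-12)
  }
})

test_that("CEAC curves sum to one and reproduce the PSA tally at the analysis WTP", {
  cfg <- table1_default_config()
  psa <- run_psa(cfg, 200, seed = 3)
  grid <- seq(0, 150000, by = 25000)
  cc <- ceac(psa, grid)
  arm_cols <- setdiff(names(cc), "wtp")
  expect_equal(unname(rowSums(cc[, arm_cols])), rep(1, nrow(cc)))
  at_wtp <- ceac(psa, cfg$policy$wtp_per_qaly)
  expect_equal(at_wtp$TM, psa$tallies$TM_vs_PE$optimal)
  # WTP-zero point: probability of being the cheapest arm
  costs <- sapply(psa$arms, `[[`, "cost")
  cheapest <- names(psa$arms)[apply(costs, 1, which.min)]
  expect_equal(cc$TM[cc$wtp == 0], mean(cheapest == "TM"))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})
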