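res_for <- function(name, cost, qalys, p = 0.5) {
  structure(list(arm_name = name, total_cost = cost, total_qalys = qalys,
                 p_respond = p),
            class = "arm_result")
}

test_that("verdicts follow the dominance sign rules", {
  a <- res_for("A", 100, 2); b <- res_for("B", 200, 1)
  expect_equal(incremental_analysis(a, b, 50000)$verdict, "dominant")
  expect_equal(incremental_analysis(b, a, 50000)$verdict, "dominated")

  c1 <- res_for("C", 300, 2)
  inc <- incremental_analysis(c1, b, 50000)
  expect_equal(inc$verdict, "icer")
  expect_equal(inc$icer_per_qaly, 100)

  same <- incremental_analysis(a, a, 50000)
  expect_equal(same$verdict, "tie")
  expect_equal(same$delta_cost, 0)
  expect_equal(same$nmb, 0)

  co <- incremental_analysis(res_for("D", 150, 1), b, 50000)
  expect_equal(co$verdict, "cost-only")
  expect_true(is.na(co$icer_per_qaly))
  expect_equal(co$note, "cost-only difference")
})

test_that("NMB is antisymmetric and positive under dominance at any WTP", {
  cfg <- table1_default_config()
  tm <- run_cohort("TM", cfg); pe <- run_cohort("PE", cfg)
  for (w in c(0, 10000, 50000, 200000)) {
    ab <- incremental_analysis(tm, pe, w)
    ba <- incremental_analysis(pe, tm, w)
    expect_equal(ab$nmb, -ba$nmb)
    expect_equal(ab$verdict, "dominant")
    expect_gt(ab$nmb, 0)
  }
})

test_that("cost per responder reproduces the published whole-dollar figures", {
  expect_equal(cost_per_responder(2822, 0.42), 6719)
  expect_equal(cost_per_responder(492, 0.32), 1538)
  expect_equal(cost_per_responder(1504, 0.61), 2466)
  expect_equal(cost_per_responder(0, 0.5), 0)
  expect_error(cost_per_responder(100, 0), "no responders")
})

test_that("optimal strategy maximizes NMB with deterministic tie-breaks", {
  cfg <- table1_default_config()
  results <- run_model(cfg)
  expect_equal(as.character(optimal_strategy(results, 50000)), "TM")
  # WTP zero: cheapest arm wins
  cheapest <- results[[which.min(vapply(results, `[[`, numeric(1), "total_cost"))]]
  expect_equal(as.character(optimal_strategy(results, 0)), cheapest$arm_name)
  # identical arms: lexicographic winner, flagged as a tie
  twins <- list(res_for("B", 100, 1), res_for("A", 100, 1))
  pick <- optimal_strategy(twins, 50000)
  expect_equal(as.character(pick), "A")
  expect_true(attr(pick, "tie"))
  # invariant to adding a constant to every arm's cost
  shifted <- lapply(results, function(r) { r$total_cost <- r$total_cost + 5000; r })
  expect_equal(as.character(optimal_strategy(shifted, 50000)),
               as.character(optimal_strategy(results, 50000)))
})

test_that("population savings scale linearly", {
  expect_equal(scale_savings(3748, 100), 374800)
  expect_equal(scale_savings(3748, 0), 0)
  expect_equal(scale_savings(0, 1e5), 0)
  expect_error(scale_savings(1, -1), ">= 0")
})

test_that("efficiency frontier drops dominated strategies", {
  cfg <- table1_default_config()
  fr <- efficiency_frontier(run_model(cfg))
  # TM dominates both comparators, so it is the whole frontier
  expect_equal(fr$arm, "TM")
  # synthetic 3-arm case with a genuine trade-off
  fr2 <- efficiency_frontier(list(res_for("cheap", 100, 1),
                                  res_for("mid", 200, 2),
                                  res_for("rich", 400, 3)))
  expect_equal(fr2$arm, c("cheap", "mid", "rich"))
  expect_equal(fr2$icer, c(NA, 100, 200))
})
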