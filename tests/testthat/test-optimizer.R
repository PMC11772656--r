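test_that("zero pacer budgets collapse to a pure solo race", {
  budgets <- simple_budgets(main = 8.5e6, strong = 0, weak = 0)
  out <- simulate_three_phase(c(5.9, 5.9, 5.8), budgets, strategy_catalog())
  expect_equal(out$phases$time_s[1:2], c(0, 0))
  expect_equal(out$phases$time_s[3], 42195 / 5.8)
  expect_equal(sum(out$phases$distance_m), 42195)
})

test_that("constant-power degenerate case matches the closed form", {
  # flat cost of running and (numerically) zero drag: every power is
  # mass * v * cost_constant, so phase times have closed forms
  eps <- 1e-9
  flat <- build_catalog(tibble::tibble(
    formation = c("SOLO", "F12", "F12", "F12", "F4", "F4"),
    position = c("MAIN", "MAIN", "P1", "P2", "MAIN", "P1"),
    a = 0, b = 0, c = eps
  ))
  params <- power_model_params(mass = 52, cost_quadratic = 0,
                               cost_constant = 3.2833)
  budgets <- simple_budgets(main = 8e6, strong = 3e6, weak = 2e6)
  v <- c(5.9, 5.7, 5.5)
  out <- simulate_three_phase(v, budgets, flat, params = params)
  cc <- 3.2833
  t1 <- 2e6 / (52 * v[1] * cc)
  t2_budget <- 3e6 - t1 * 52 * v[1] * cc # strong spends at the same flat rate
  t2 <- t2_budget / (52 * v[2] * cc)
  expect_equal(out$phases$time_s[1], t1, tolerance = 1e-9)
  expect_equal(out$phases$time_s[2], t2, tolerance = 1e-9)
  d3 <- 42195 - v[1] * t1 - v[2] * t2
  expect_equal(out$phases$time_s[3], d3 / v[3], tolerance = 1e-9)
})

test_that("pacers outlasting the race distance flag the outcome infeasible", {
  budgets <- simple_budgets(main = 9e6, strong = 6e7, weak = 6e7)
  out <- simulate_three_phase(c(6, 6, 6), budgets, strategy_catalog())
  expect_false(out$feasible)
  expect_equal(sum(out$phases$distance_m), 42195)
})

test_that("optimum satisfies energy exhaustion and distance closure", {
  for (year in c(2018, 2022)) {
    budgets <- berlin_budgets(year)
    out <- optimize_strategy(budgets)
    expect_true(out$feasible)
    expect_equal(sum(out$phases$distance_m), 42195, tolerance = 1e-9)
    expect_equal(out$phases$time_s,
                 out$phases$distance_m / out$phases$speed_mps)
    expect_equal(out$total_time, sum(out$phases$time_s))
    # pacers leave with empty tanks; the main runner's equality holds
    expect_equal(out$energy$spent_J, out$energy$budget_J, tolerance = 1e-6)
    expect_lt(abs(out$residual_J), 10)
  }
})

test_that("both Berlin scenarios optimize to sub-two-hour positive splits", {
  for (year in c(2018, 2022)) {
    out <- optimize_strategy(berlin_budgets(year))
    expect_lte(out$total_time_ceil, 7200)
    diag <- splitting_diagnosis(out)
    expect_equal(diag$splitting, "positive")
    v <- out$phases$speed_mps
    expect_true(v[1] >= v[2] && v[2] >= v[3] && v[1] > v[3])
  }
})

test_that("optimizer matches the brute-force grid oracle on the Berlin data", {
  for (year in c(2018, 2022)) {
    budgets <- berlin_budgets(year)
    out <- optimize_strategy(budgets)
    oracle <- grid_oracle(budgets, default_catalog())
    expect_lte(out$total_time, oracle$total + 0.5)
  }
})

test_that("optimizer is deterministic under a fixed seed", {
  budgets <- berlin_budgets(2022)
  a <- optimize_strategy(budgets, settings = optimizer_settings(seed = 7))
  b <- optimize_strategy(budgets, settings = optimizer_settings(seed = 7))
  expect_identical(glance(a), glance(b))
})

test_that("raising the main runner's budget never slows the optimum", {
  # under strict equality a big enough budget cannot be burnt inside the
  # speed bounds at all, so monotonicity is a statement about the
  # inequality variant (spend at most the budget)
  relaxed <- strategy_config(energy_constraint = "inequality")
  budgets <- berlin_budgets(2022)
  base <- optimize_strategy(budgets, config = relaxed)$total_time
  prev <- base
  for (f in c(1.02, 1.05, 1.2)) {
    up <- budgets
    up$budget_J[up$runner == "Eliud Kipchoge"] <-
      f * up$budget_J[up$runner == "Eliud Kipchoge"]
    t_up <- optimize_strategy(up, config = relaxed)$total_time
    expect_lte(t_up, prev + 1e-6)
    prev <- t_up
  }
  # with a binding budget the equality and inequality optima coincide
  strict <- optimize_strategy(budgets)$total_time
  expect_equal(base, strict, tolerance = 1e-6)
})

test_that("infeasible scenarios fail with a diagnostic error", {
  # a tiny main budget cannot cover the marathon inside the speed bounds
  budgets <- simple_budgets(main = 1e6, strong = 5e5, weak = 3e5)
  expect_error(optimize_strategy(budgets, strategy_catalog()),
               "no feasible")
})

test_that("cooperative variant is a no-op for symmetric pacer curves", {
  sym <- strategy_catalog(lead = 0.7, trail12 = 0.7)
  budgets <- simple_budgets()
  res <- cooperative_variant(budgets, sym)
  expect_equal(res$delta_time_s, 0)
})

test_that("cooperative pacer swap saves time when positions differ", {
  for (year in c(2018, 2022)) {
    res <- cooperative_variant(berlin_budgets(year))
    expect_gt(res$delta_time_s, 0)
    expect_lt(res$delta_time_s, 5)
    expect_true(res$outcome$feasible)
  }
})

test_that("splitting diagnosis labels the published speed patterns", {
  fake <- function(v) {
    structure(list(phases = tibble::tibble(
      phase = 1:3, formation = c("F12", "F4", "SOLO"),
      speed_mps = v, time_s = 1, distance_m = v
    )), class = "race_outcome")
  }
  pos <- splitting_diagnosis(fake(c(5.967, 5.923, 5.743)))
  expect_equal(pos$splitting, "positive")
  expect_equal(pos$phase3_deficit, 0.034, tolerance = 0.01)
  expect_equal(splitting_diagnosis(fake(c(5.7, 5.8, 5.9)))$splitting, "negative")
  expect_equal(splitting_diagnosis(fake(c(5.8, 5.8, 5.8)))$splitting, "even")
})

test_that("race outcomes tidy and glance coherently", {
  out <- optimize_strategy(berlin_budgets(2022))
  td <- tidy(out)
  expect_equal(nrow(td), 3)
  gl <- glance(out)
  expect_equal(gl$total_time_s, sum(td$time_s))
  expect_equal(gl$splitting, "positive")
  expect_true(gl$feasible)
})
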