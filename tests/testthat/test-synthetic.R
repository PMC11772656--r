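test_that("noise-free synthetic catalogs recover scaled solo polynomials exactly", {
  gen <- generate_catalog(synthetic_spec(seed = 5, noise_sd = 0))
  samples <- gen$samples
  cat <- tibble::as_tibble(gen$catalog)
  reductions <- dplyr::distinct(samples, formation, position, reduction)
  joined <- dplyr::inner_join(cat, reductions, by = c("formation", "position"))
  expect_equal(joined$a, (1 - joined$reduction) * 0.493, tolerance = 1e-9)
  expect_equal(joined$b, (1 - joined$reduction) * -3.256, tolerance = 1e-9)
  expect_equal(joined$c, (1 - joined$reduction) * 7.878, tolerance = 1e-9)
})

test_that("generator output is a deterministic function of the seed", {
  spec <- synthetic_spec(seed = 9, noise_sd = 0.05)
  a <- generate_catalog(spec)
  b <- generate_catalog(spec)
  expect_identical(a$samples, b$samples)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_catalog_csv(a$catalog, p1)
  write_catalog_csv(b$catalog, p2)
  expect_identical(readLines(p1), readLines(p2))

  fx1 <- generate_race_fixture(spec)
  fx2 <- generate_race_fixture(spec)
  expect_identical(fx1$splits, fx2$splits)

  different <- generate_catalog(synthetic_spec(seed = 10, noise_sd = 0.05))
  expect_false(identical(a$samples$drag, different$samples$drag))
})

test_that("noisy fits are unbiased with the spread least-squares theory predicts", {
  sd_noise <- 0.05
  n_rep <- 100
  v <- unname(cfd_speed_grid)
  fits <- t(vapply(seq_len(n_rep), function(s) {
    set.seed(1000 + s)
    drag <- solo_poly(v) + rnorm(4, 0, sd_noise)
    f <- fit_drag_curve(tibble::tibble(v = v, drag = drag))
    c(f$a, f$b, f$c)
  }, numeric(3)))
  truth <- c(0.493, -3.256, 7.878)
  # closed-form least-squares covariance: sigma^2 (X'X)^-1
  X <- cbind(v^2, v, 1)
  cov_theory <- sd_noise^2 * solve(t(X) %*% X)
  se_mean <- sqrt(diag(cov_theory) / n_rep)
  bias <- colMeans(fits) - truth
  expect_true(all(abs(bias) < 4 * se_mean))
  sd_emp <- apply(fits, 2, sd)
  sd_theory <- sqrt(diag(cov_theory))
  expect_true(all(sd_emp / sd_theory > 0.6 & sd_emp / sd_theory < 1.6))
})

test_that("generated race fixtures always parse cleanly and close the distance", {
  for (seed in 1:8) {
    fx <- generate_race_fixture(synthetic_spec(seed = seed,
                                               n_phases = 3 + seed %% 2))
    expect_no_warning(phases <- parse_splits(fx$splits))
    expect_equal(sum(phases$distance_m), 42195, tolerance = 1e-9)
    expect_true(all(phases$speed_mps >= 5.2 & phases$speed_mps <= 6.0))
    expect_true(all(phases$duration_s > 0))
    # formations shrink as pacers drop; the race ends solo
    expect_equal(phases$formation[nrow(phases)], "SOLO")
  }
})

test_that("paper-mode fixtures reproduce the shipped transcriptions byte for byte", {
  for (year in c(2018, 2022)) {
    fx <- generate_race_fixture(paper_mode = year)
    tmp <- withr::local_tempfile(fileext = ".csv")
    readr::write_csv(fx$splits, tmp)
    shipped <- system.file("extdata", sprintf("berlin%d_splits.csv", year),
                           package = "pacedraft")
    expect_identical(readLines(tmp), readLines(shipped))
    tmp2 <- withr::local_tempfile(fileext = ".csv")
    readr::write_csv(fx$roster, tmp2)
    shipped2 <- system.file("extdata", sprintf("berlin%d_roster.csv", year),
                            package = "pacedraft")
    expect_identical(readLines(tmp2), readLines(shipped2))
  }
})

test_that("synthetic scenarios run end to end and respect the grid oracle", {
  # a deeper 20-seed sweep of the same property runs in the acceptance suite
  for (seed in 1:6) {
    sc <- generate_scenario(synthetic_spec(seed = seed))
    out <- optimize_strategy(sc$budgets, sc$catalog, sc$config, sc$settings)
    expect_true(out$feasible)
    expect_equal(sum(out$phases$distance_m), 42195, tolerance = 1e-9)
    expect_equal(out$energy$spent_J, out$energy$budget_J, tolerance = 1e-6)
    oracle <- grid_oracle(sc$budgets, sc$catalog)
    expect_lte(out$total_time, oracle$total + 0.5)
  }
})

test_that("equal pacer curves give a zero cooperative delta on synthetic data", {
  sc <- generate_scenario(synthetic_spec(seed = 3))
  cat <- tibble::as_tibble(sc$catalog)
  p1 <- cat$formation == "F12" & cat$position == "P1"
  p2 <- cat$formation == "F12" & cat$position == "P2"
  cat[p2, c("a", "b", "c")] <- cat[p1, c("a", "b", "c")]
  sym <- build_catalog(cat[, c("formation", "position", "a", "b", "c")])
  res <- cooperative_variant(sc$budgets, sym, sc$config, sc$settings)
  expect_equal(res$delta_time_s, 0)
})

test_that("richer pacer budgets strictly speed up the optimal race", {
  # modest boosts keep the pacers inside the race distance, where the
  # three-phase strategy is well defined; more drafting time can then only
  # help the main runner
  # longer drafting leaves the main runner with energy he cannot burn
  # in-bounds, so budget sensitivity uses the inequality variant
  sc <- generate_scenario(synthetic_spec(seed = 6))
  relaxed <- strategy_config(energy_constraint = "inequality")
  base <- optimize_strategy(sc$budgets, sc$catalog, relaxed, sc$settings)
  main <- sc$budgets$runner[which.max(sc$budgets$budget_J)]
  prev <- base$total_time
  for (f in c(1.1, 1.2)) {
    rich <- sc$budgets
    rich$budget_J[rich$runner != main] <- f * rich$budget_J[rich$runner != main]
    boosted <- optimize_strategy(rich, sc$catalog, relaxed, sc$settings)
    expect_lt(boosted$total_time, prev)
    expect_lte(boosted$total_time, grid_oracle(rich, sc$catalog)$total + 0.5)
    prev <- boosted$total_time
  }
})

test_that("synthetic spec validates its invariants", {
  expect_error(synthetic_spec(reduction_range = c(0.2, 0.99)))
  expect_error(synthetic_spec(noise_sd = -1))
  expect_error(synthetic_spec(speed_grid = c(5.9, 5.5, 5.2, 5.0)))
})
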