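# Independent brute-force oracle for the three-phase race-time minimum.
#
# Evaluates every (v1, v2, v3) combination on a regular grid with fully
# vectorised closed-form arithmetic (no optimizer, no root-finding) and
# returns the best total among energy-admissible points: the main runner
# may not overspend his budget (residual >= 0) and the solo distance must
# be non-negative. Because spending the whole budget is optimal whenever
# the phase-3 speed is interior, the admissible grid minimum brackets the
# equality-constrained optimum from above.
grid_oracle <- function(budgets, catalog, step = 0.02, bounds = c(5, 6),
                        distance = 42195, cooperative = FALSE) {
  budgets <- dplyr::arrange(budgets, dplyr::desc(budget_J))
  main <- budgets[1, ]; strong <- budgets[2, ]; weak <- budgets[3, ]
  coefs <- function(f, p) {
    row <- tibble::as_tibble(catalog)
    row <- row[row$formation == f & row$position == p, ]
    c(row$a, row$b, row$c)
  }
  pw <- function(v, m, q) {
    qs <- coefs("SOLO", "MAIN")
    m * v * (0.018 * v^2 + 3.2833) -
      v * (qs[1] * v^2 + qs[2] * v + qs[3]) +
      v * (q[1] * v^2 + q[2] * v + q[3])
  }
  g <- seq(bounds[1], bounds[2], by = step)
  grid <- expand.grid(v1 = g, v2 = g, v3 = g)
  P_lead <- pw(grid$v1, strong$mass_kg, coefs("F12", "P1"))
  P_trail_wk <- pw(grid$v1, weak$mass_kg, coefs("F12", "P2"))
  if (cooperative) {
    P_wk1 <- 0.5 * (pw(grid$v1, weak$mass_kg, coefs("F12", "P1")) + P_trail_wk)
    P_str1 <- 0.5 * (P_lead + pw(grid$v1, strong$mass_kg, coefs("F12", "P2")))
  } else {
    P_wk1 <- P_trail_wk
    P_str1 <- P_lead
  }
  t1 <- weak$budget_J / P_wk1
  e_str <- strong$budget_J - t1 * P_str1
  t2 <- pmax(e_str, 0) / pw(grid$v2, strong$mass_kg, coefs("F4", "P1"))
  d3 <- distance - grid$v1 * t1 - grid$v2 * t2
  t3 <- d3 / grid$v3
  spent_main <- t1 * pw(grid$v1, main$mass_kg, coefs("F12", "MAIN")) +
    t2 * pw(grid$v2, main$mass_kg, coefs("F4", "MAIN")) +
    t3 * pw(grid$v3, main$mass_kg, coefs("SOLO", "MAIN"))
  ok <- d3 >= 0 & spent_main <= main$budget_J
  total <- t1 + t2 + t3
  total[!ok] <- Inf
  i <- which.min(total)
  list(total = total[i], v = as.numeric(grid[i, ]))
}
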