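#' Three-phase race strategy configuration
#'
#' Describes the projected race the optimizer searches over: start in
#' Formation 12 (one pacer ahead of the main runner, one behind) until the
#' weaker pacer has spent his budget, switch to Formation 4 (remaining
#' pacer directly ahead) until the second pacer is exhausted, finish solo.
#' Phase speeds are bounded to the window in which the drag curves were
#' fitted.
#'
#' @param phase_formations Ordered formation ids for the three phases.
#' @param v_bounds Lower/upper speed bounds, m/s.
#' @param race_distance Race distance, m.
#' @param rounding `"ceil_seconds"` to report the total rounded up to the
#'   next whole second (race-clock convention) alongside the raw value, or
#'   `"none"`.
#' @param cooperative If `TRUE`, phase 1 is modelled as two equal-duration
#'   halves with the two pacers exchanging the front and rear positions at
#'   the midpoint, so each spends at the mean of the two positional powers.
#' @param limiting_key Catalog key (formation, position) whose curve prices
#'   the limiting pacer's phase-1 power.
#' @param energy_constraint `"equality"` enforces the conservation rule as
#'   stated -- the main runner's remaining energy after the paced phases
#'   exactly equals the solo-phase spend. `"inequality"` allows him to
#'   finish with unspent energy when even the fastest admissible solo
#'   speed cannot burn it, which is the variant to use for sensitivity
#'   runs (e.g. inflating budgets).
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(phase_formations = c("F12", "F4", "SOLO"),
                            v_bounds = c(5, 6),
                            race_distance = marathon_distance_m,
                            rounding = c("ceil_seconds", "none"),
                            cooperative = FALSE,
                            limiting_key = c(formation = "F12", position = "P2"),
                            energy_constraint = c("equality", "inequality")) {
  stopifnot(length(phase_formations) == 3, length(v_bounds) == 2,
            v_bounds[1] < v_bounds[2], race_distance > 0)
  structure(
    list(
      phase_formations = phase_formations,
      v_bounds = as.numeric(v_bounds),
      race_distance = race_distance,
      rounding = match.arg(rounding),
      cooperative = isTRUE(cooperative),
      limiting_key = limiting_key,
      energy_constraint = match.arg(energy_constraint)
    ),
    class = "strategy_config"
  )
}

#' Optimizer settings
#'
#' @param n_starts Number of Latin-hypercube multistart points for the
#'   phase-1/phase-2 speed search.
#' @param objective_tol Convergence tolerance on total time, s.
#' @param constraint_tol Acceptable residual on the main runner's energy
#'   equality constraint, J.
#' @param seed Integer seed making the multistart deterministic.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(n_starts = 8, objective_tol = 1e-8,
                               constraint_tol = 10, seed = 1) {
  stopifnot(n_starts >= 1, objective_tol > 0, constraint_tol > 0)
  structure(
    list(n_starts = as.integer(n_starts), objective_tol = objective_tol,
         constraint_tol = constraint_tol, seed = as.integer(seed)),
    class = "optimizer_settings"
  )
}

# Resolve main / strong pacer / weak pacer roles from a budgets table.
# The main runner is taken explicitly or as the largest budget; among the
# pacers, the limiting (weak) one is the smaller budget-to-power ratio at
# speed v_ref with the limiting-position curve -- for equal masses this is
# simply the smaller budget, but the ratio form stays correct when pacer
# power curves differ.
resolve_roles <- function(budgets, catalog, config, main_runner = NULL,
                          v_ref = NULL) {
  budgets <- tibble::as_tibble(budgets)
  if (!all(c("runner", "mass_kg", "budget_J") %in% names(budgets))) {
    abort("budgets need columns `runner`, `mass_kg`, `budget_J`.")
  }
  if (nrow(budgets) < 3) abort("need a main runner and two pacers.")
  main <- main_runner %||% budgets$runner[which.max(budgets$budget_J)]
  pacers <- dplyr::filter(budgets, .data$runner != main) |>
    dplyr::slice_max(.data$budget_J, n = 2, with_ties = FALSE)
  v_ref <- v_ref %||% mean(config$v_bounds)
  solo_curve <- catalog_curve(catalog, "SOLO", "MAIN")
  lim_curve <- catalog_curve(catalog, config$limiting_key[["formation"]],
                             config$limiting_key[["position"]])
  ratio <- vapply(seq_len(2), function(i) {
    p <- power_model_params(mass = pacers$mass_kg[i], solo_drag_curve = solo_curve)
    pacers$budget_J[i] / runner_power(v_ref, p, lim_curve)
  }, numeric(1))
  weak_i <- which.min(ratio)
  list(
    main = dplyr::filter(budgets, .data$runner == main),
    strong = pacers[-weak_i, ],
    weak = pacers[weak_i, ]
  )
}

# Compile budgets + catalog + config into a fast numeric simulator.
# All catalog lookups, validation and per-runner parameter construction
# happen once; the returned function is plain polynomial arithmetic, which
# keeps the optimizer's inner loop (and the brute-force oracle) cheap.
three_phase_engine <- function(budgets, catalog, config, main_runner = NULL,
                               params = power_model_params()) {
  roles <- resolve_roles(budgets, catalog, config, main_runner)
  f1 <- config$phase_formations[1]; f2 <- config$phase_formations[2]
  f3 <- config$phase_formations[3]
  solo <- catalog_curve(catalog, "SOLO", "MAIN")
  cv <- function(f, pos) {
    cu <- catalog_curve(catalog, f, pos)
    c(cu$a, cu$b, cu$c)
  }
  qe <- function(q, v) q[1] * v^2 + q[2] * v + q[3]
  soloq <- c(solo$a, solo$b, solo$c)
  cq <- params$cost_quadratic; cc <- params$cost_constant
  # P(v) for mass m with positional quadratic q
  pw <- function(m, q) {
    force(m); force(q)
    function(v) m * v * (cq * v^2 + cc) - v * qe(soloq, v) + v * qe(q, v)
  }
  P <- list(
    main1 = pw(roles$main$mass_kg, cv(f1, "MAIN")),
    main2 = pw(roles$main$mass_kg, cv(f2, "MAIN")),
    main3 = pw(roles$main$mass_kg, cv(f3, "MAIN")),
    str_lead1 = pw(roles$strong$mass_kg, cv(f1, "P1")),
    str_trail1 = pw(roles$strong$mass_kg, cv(f1, "P2")),
    wk_lead1 = pw(roles$weak$mass_kg, cv(f1, "P1")),
    wk_trail1 = pw(roles$weak$mass_kg, cv(f1, "P2")),
    str2 = pw(roles$strong$mass_kg, cv(f2, "P1"))
  )
  D <- config$race_distance
  E <- c(main = roles$main$budget_J, strong = roles$strong$budget_J,
         weak = roles$weak$budget_J)
  cooperative <- config$cooperative
  sim <- function(v) {
    if (cooperative) {
      P_wk1 <- 0.5 * (P$wk_lead1(v[1]) + P$wk_trail1(v[1]))
      P_str1 <- 0.5 * (P$str_lead1(v[1]) + P$str_trail1(v[1]))
    } else {
      P_wk1 <- P$wk_trail1(v[1])
      P_str1 <- P$str_lead1(v[1])
    }
    if (P_wk1 <= 0 || P_str1 <= 0) abort("degenerate zero-power input.")
    feasible <- TRUE
    t1 <- E[["weak"]] / P_wk1
    if (v[1] * t1 > D) { t1 <- D / v[1]; feasible <- FALSE }
    e_str <- E[["strong"]] - t1 * P_str1
    e_main <- E[["main"]] - t1 * P$main1(v[1])
    P_str2 <- P$str2(v[2])
    t2 <- max(e_str, 0) / P_str2
    if (v[1] * t1 + v[2] * t2 > D) {
      t2 <- max(D - v[1] * t1, 0) / v[2]
      feasible <- FALSE
    }
    e_main <- e_main - t2 * P$main2(v[2])
    d3 <- D - v[1] * t1 - v[2] * t2
    if (d3 < -1e-9) feasible <- FALSE
    d3 <- max(d3, 0)
    t3 <- d3 / v[3]
    residual <- e_main - t3 * P$main3(v[3])
    list(
      t = c(t1, t2, t3), d = c(v[1] * t1, v[2] * t2, d3),
      total = t1 + t2 + t3, residual = residual, feasible = feasible,
      spent = c(main = E[["main"]] - residual,
                strong = t1 * P_str1 + t2 * P_str2,
                weak = t1 * P_wk1)
    )
  }
  list(sim = sim, roles = roles, config = config)
}

engine_outcome <- function(engine, v) {
  s <- engine$sim(v)
  config <- engine$config
  roles <- engine$roles
  phases <- tibble::tibble(
    phase = 1:3,
    formation = config$phase_formations,
    speed_mps = as.numeric(v),
    time_s = s$t,
    distance_m = s$d
  )
  energy <- tibble::tibble(
    runner = c(roles$main$runner, roles$strong$runner, roles$weak$runner),
    role = c("main", "pacer_strong", "pacer_weak"),
    budget_J = c(roles$main$budget_J, roles$strong$budget_J,
                 roles$weak$budget_J),
    spent_J = unname(s$spent)
  )
  structure(
    list(
      phases = phases, energy = energy,
      total_time = s$total, total_time_ceil = ceiling(s$total),
      residual_J = s$residual, feasible = s$feasible,
      cooperative = config$cooperative, config = config
    ),
    class = "race_outcome"
  )
}

#' Simulate the three-phase projected race at fixed phase speeds
#'
#' Forward-simulates the strategy of [strategy_config()] at given phase
#' speeds. Phase 1 lasts until the weaker pacer's budget is exhausted at
#' his phase-1 power (`t1 = E_weak / P_weak(v1)`); phase 2 until the
#' stronger pacer's remaining budget is exhausted leading Formation 4; the
#' remaining distance is run solo at `v3`. The main runner's energy
#' equality constraint (spend exactly the budget) is *reported* as a
#' residual, not enforced here -- [optimize_strategy()] closes it.
#'
#' If the pacers would outlast the race distance the pacer phases are
#' truncated at the finish line and the outcome is flagged infeasible for
#' the three-phase strategy.
#'
#' @param v Numeric length-3: phase speeds (v1, v2, v3), m/s.
#' @param budgets A tibble with columns `runner`, `mass_kg`, `budget_J`
#'   (e.g. from [budgets_from_actual_race()]).
#' @param catalog A `drag_catalog` containing `F12` (`MAIN`,`P1`,`P2`),
#'   `F4` (`MAIN`,`P1`) and `SOLO`/`MAIN` entries.
#' @param config A [strategy_config()].
#' @param main_runner Name of the main runner; default: largest budget.
#' @param params A [power_model_params()] supplying the cost-of-running
#'   coefficients; masses come from `budgets` and the aerodynamic terms
#'   from `catalog` (its `SOLO`/`MAIN` entry is the reference that is
#'   subtracted back out).
#' @return A `race_outcome` object: per-phase tibble (speed, time,
#'   distance, formation), per-runner energy table, raw and ceil-rounded
#'   total time, the main runner's energy residual (J) and a feasibility
#'   flag.
#' @examples
#' ph <- parse_splits(berlin_splits(2022))
#' b <- budgets_from_actual_race(ph, berlin_roster(2022), berlin_exposure(2022))
#' simulate_three_phase(c(5.97, 5.92, 5.74), b)
#' @export
simulate_three_phase <- function(v, budgets, catalog = default_catalog(),
                                 config = strategy_config(),
                                 main_runner = NULL,
                                 params = power_model_params()) {
  stopifnot(length(v) == 3, all(is.finite(v)), all(v > 0))
  engine <- three_phase_engine(budgets, catalog, config, main_runner, params)
  engine_outcome(engine, v)
}

#' @export
print.race_outcome <- function(x, ...) {
  cat(sprintf(
    "<race_outcome%s> total %.2f s (%d s on the clock), %s, residual %.3g J\n",
    if (x$cooperative) " cooperative" else "",
    x$total_time, x$total_time_ceil,
    if (x$feasible) "feasible" else "INFEASIBLE", x$residual_J
  ))
  print(x$phases)
  invisible(x)
}

#' @export
tidy.race_outcome <- function(x, ...) x$phases

#' @export
glance.race_outcome <- function(x, ...) {
  diag <- splitting_diagnosis(x)
  tibble::tibble(
    total_time_s = x$total_time,
    total_time_ceil_s = x$total_time_ceil,
    mean_speed_mps = sum(x$phases$distance_m) / x$total_time,
    residual_J = x$residual_J,
    feasible = x$feasible,
    cooperative = x$cooperative,
    splitting = diag$splitting,
    phase3_deficit = diag$phase3_deficit
  )
}

# Solve v3 in [lo, hi] so that the main runner's energy residual vanishes.
# Returns NA when the equality cannot be met inside the bounds.
close_v3 <- function(engine, v12, bounds) {
  g <- function(v3) engine$sim(c(v12, v3))$residual
  glo <- g(bounds[1]); ghi <- g(bounds[2])
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(NA_real_)
  uniroot(g, bounds, tol = 1e-12)$root
}

#' Minimise projected race time under energy conservation
#'
#' Finds the phase speeds (v1, v2, v3) in the bounds box that minimise
#' total race time `t1 + t2 + t3` subject to the main runner spending
#' exactly his energy budget and the solo distance being non-negative. The
#' pacer-exhaustion equalities hold by construction of the phase times, so
#' the search runs over (v1, v2) with v3 obtained by root-finding on the
#' main runner's energy residual; a Latin-hypercube multistart (seeded,
#' deterministic) guards against local minima of the bounded
#' quasi-Newton refinement.
#'
#' @inheritParams simulate_three_phase
#' @param settings An [optimizer_settings()].
#' @return The optimal feasible `race_outcome`, with the multistart table
#'   attached as attribute `"starts"`.
#' @examples
#' ph <- parse_splits(berlin_splits(2022))
#' b <- budgets_from_actual_race(ph, berlin_roster(2022), berlin_exposure(2022))
#' opt <- optimize_strategy(b)
#' glance(opt)
#' @export
optimize_strategy <- function(budgets, catalog = default_catalog(),
                              config = strategy_config(),
                              settings = optimizer_settings(),
                              main_runner = NULL,
                              params = power_model_params()) {
  lo <- config$v_bounds[1]; hi <- config$v_bounds[2]
  engine <- three_phase_engine(budgets, catalog, config, main_runner, params)
  # The main runner's phase-3 energy residual decreases in v3 (running the
  # remaining distance faster costs more), so the equality has a root iff
  # residual(lo) >= 0 >= residual(hi). Where no root exists the objective
  # is penalised in proportion to the violation, which keeps the search
  # smooth and pointed back toward the feasible manifold.
  inequality <- identical(config$energy_constraint, "inequality")
  objective <- function(v12) {
    s_lo <- engine$sim(c(v12, lo)); s_hi <- engine$sim(c(v12, hi))
    if (!s_lo$feasible && !s_hi$feasible) return(1e9)
    if (s_hi$residual > 0) {
      # surplus energy even at the speed cap: admissible under the
      # inequality variant, a penalised violation under strict equality
      return(if (inequality) s_hi$total else s_hi$total + 1e-2 * s_hi$residual)
    }
    if (s_lo$residual < 0) return(s_lo$total - 1e-2 * s_lo$residual)
    v3 <- close_v3(engine, v12, c(lo, hi))
    if (is.na(v3)) return(1e9)
    s <- engine$sim(c(v12, v3))
    if (!s$feasible) return(1e9)
    s$total
  }
  set.seed(settings$seed)
  starts <- lhs::randomLHS(settings$n_starts, 2) * (hi - lo) + lo
  runs <- purrr::map(seq_len(settings$n_starts), function(i) {
    fit <- optim(starts[i, ], objective,
      method = "L-BFGS-B", lower = c(lo, lo), upper = c(hi, hi),
      control = list(factr = settings$objective_tol / .Machine$double.eps)
    )
    tibble::tibble(start_v1 = starts[i, 1], start_v2 = starts[i, 2],
                   v1 = fit$par[1], v2 = fit$par[2], total = fit$value)
  })
  runs <- dplyr::bind_rows(runs)
  best <- runs[which.min(runs$total), ]
  if (!is.finite(best$total) || best$total >= 1e9) {
    abort(paste(
      "no feasible (v1, v2, v3) found: the energy-equality constraint",
      "cannot be met inside the speed bounds. Check budgets and catalog."
    ))
  }
  v12 <- c(best$v1, best$v2)
  v3 <- close_v3(engine, v12, c(lo, hi))
  if (is.na(v3)) {
    if (inequality && engine$sim(c(v12, hi))$residual > 0) {
      v3 <- hi
    } else {
      abort(paste(
        "no feasible (v1, v2, v3) found: the energy-equality constraint",
        "cannot be met inside the speed bounds. Check budgets and catalog."
      ))
    }
  }
  out <- engine_outcome(engine, c(v12, v3))
  violation <- if (inequality) -out$residual_J else abs(out$residual_J)
  if (violation > settings$constraint_tol) {
    abort(sprintf(
      "energy constraint residual %.3g J exceeds tolerance %.3g J.",
      out$residual_J, settings$constraint_tol
    ))
  }
  attr(out, "starts") <- runs
  out
}

#' Cooperative-drafting variant of the optimum
#'
#' Re-optimises the projected race with phase 1 split into two equal
#' halves in which the pacers exchange the front and rear positions of
#' Formation 12, sharing the drag burden (each spends at the mean of the
#' two positional powers). Returns the cooperative optimum and its saving
#' over the standard optimum; with identical front and rear curves the
#' swap is a no-op and the saving is exactly zero.
#'
#' @inheritParams optimize_strategy
#' @return A list with elements `outcome` (the cooperative `race_outcome`),
#'   `baseline` (the non-cooperative one) and `delta_time_s`
#'   (baseline total minus cooperative total, s).
#' @examples
#' ph <- parse_splits(berlin_splits(2022))
#' b <- budgets_from_actual_race(ph, berlin_roster(2022), berlin_exposure(2022))
#' cooperative_variant(b)$delta_time_s
#' @export
cooperative_variant <- function(budgets, catalog = default_catalog(),
                                config = strategy_config(),
                                settings = optimizer_settings(),
                                main_runner = NULL,
                                params = power_model_params()) {
  config_base <- config; config_base$cooperative <- FALSE
  config_coop <- config; config_coop$cooperative <- TRUE
  base <- optimize_strategy(budgets, catalog, config_base, settings,
                            main_runner, params)
  coop <- optimize_strategy(budgets, catalog, config_coop, settings,
                            main_runner, params)
  list(
    outcome = coop,
    baseline = base,
    delta_time_s = base$total_time - coop$total_time
  )
}

#' Classify the pacing profile of an outcome
#'
#' Positive splitting means running the early, pacer-assisted phases
#' faster than the solo finale (`v1 >= v2 >= v3`, strictly somewhere);
#' negative splitting the reverse; even pacing neither. Also reports the
#' phase-3 speed deficit `1 - v3 / mean(v1, v2)`.
#'
#' @param outcome A `race_outcome`.
#' @return A one-row tibble with columns `splitting`
#'   (`"positive"`/`"negative"`/`"even"`) and `phase3_deficit` (fraction).
#' @export
splitting_diagnosis <- function(outcome) {
  v <- outcome$phases$speed_mps
  label <- if (v[1] >= v[2] && v[2] >= v[3] && (v[1] > v[2] || v[2] > v[3])) {
    "positive"
  } else if (v[1] <= v[2] && v[2] <= v[3] && (v[1] < v[2] || v[2] < v[3])) {
    "negative"
  } else {
    "even"
  }
  tibble::tibble(
    splitting = label,
    phase3_deficit = 1 - v[3] / mean(v[1:2])
  )
}
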