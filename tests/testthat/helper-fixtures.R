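# Shared fixtures built in code.

solo_coefs <- c(a = 0.493, b = -3.256, c = 7.878)

solo_poly <- function(v) {
  solo_coefs[["a"]] * v^2 + solo_coefs[["b"]] * v + solo_coefs[["c"]]
}

# catalog whose every curve is the solo polynomial scaled by a multiplier
scaled_catalog <- function(mults) {
  stopifnot(!is.null(names(mults)))
  parts <- strsplit(names(mults), "/", fixed = TRUE)
  build_catalog(tibble::tibble(
    formation = vapply(parts, `[`, "", 1),
    position = vapply(parts, `[`, "", 2),
    a = unname(mults) * solo_coefs[["a"]],
    b = unname(mults) * solo_coefs[["b"]],
    c = unname(mults) * solo_coefs[["c"]]
  ))
}

# minimal catalog for the three-phase strategy, spec'd by multipliers
strategy_catalog <- function(main12 = 0.38, main4 = 0.46, lead = 0.97,
                             trail12 = 0.45) {
  scaled_catalog(c(
    "SOLO/MAIN" = 1, "F12/MAIN" = main12, "F12/P1" = lead,
    "F12/P2" = trail12, "F4/MAIN" = main4, "F4/P1" = lead
  ))
}

simple_budgets <- function(main = 8.5e6, strong = 5.2e6, weak = 3.2e6,
                           mass = 52) {
  tibble::tibble(
    runner = c("Main", "Strong", "Weak"),
    mass_kg = mass,
    budget_J = c(main, strong, weak)
  )
}

berlin_budgets <- function(year, catalog = default_catalog()) {
  phases <- parse_splits(berlin_splits(year))
  budgets_from_actual_race(phases, berlin_roster(year),
                           berlin_exposure(year), catalog)
}
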