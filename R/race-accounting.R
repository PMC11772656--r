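parse_hms <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 2) p <- c(0, p)
    if (length(p) != 3 || any(is.na(p))) {
      abort(sprintf("cannot parse time '%s' (expected hh:mm:ss).",
                    paste(p, collapse = ":")))
    }
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

format_hms <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Parse a race split table into per-phase records
#'
#' Turns a cumulative split table -- one row per formation phase with the
#' cumulative elapsed time (`hh:mm:ss`) and cumulative distance (km) at the
#' end of the phase -- into per-phase durations, distances and speeds. When
#' the table carries a printed `speed_mps` column, the recomputed speed is
#' cross-checked against it and any row disagreeing by more than
#' 0.002 m/s triggers a warning naming the row.
#'
#' @param x A file path to a splits CSV or a data frame with columns
#'   `cum_time` (hh:mm:ss), `cum_distance_km`, `formation` and optionally
#'   `speed_mps`.
#' @return A `race_phases` tibble with columns `phase`, `duration_s`,
#'   `distance_m`, `speed_mps`, `formation`.
#' @examples
#' parse_splits(berlin_splits(2018))
#' @export
parse_splits <- function(x) {
  raw <- if (is.character(x) && length(x) == 1) {
    readr::read_csv(x, show_col_types = FALSE,
                    col_types = readr::cols(cum_time = readr::col_character()))
  } else {
    tibble::as_tibble(x)
  }
  needed <- c("cum_time", "cum_distance_km", "formation")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("splits table needs columns: %s.", paste(needed, collapse = ", ")))
  }
  cum_t <- parse_hms(raw$cum_time)
  cum_d <- raw$cum_distance_km * 1000
  if (any(diff(cum_t) <= 0) || any(diff(cum_d) <= 0)) {
    abort("cumulative time and distance must be strictly increasing.")
  }
  dur <- diff(c(0, cum_t))
  dist <- diff(c(0, cum_d))
  speed <- dist / dur
  if ("speed_mps" %in% names(raw)) {
    off <- which(abs(speed - raw$speed_mps) > 0.002)
    for (i in off) {
      warn(sprintf(
        "row %d: recomputed speed %.4f m/s disagrees with printed %.4f m/s.",
        i, speed[i], raw$speed_mps[i]
      ))
    }
  }
  out <- tibble::tibble(
    phase = seq_along(dur),
    duration_s = dur,
    distance_m = dist,
    speed_mps = speed,
    formation = as.character(raw$formation)
  )
  class(out) <- c("race_phases", class(out))
  out
}

#' Write a splits table to CSV
#'
#' Serialises per-phase records back to the cumulative CSV schema read by
#' [parse_splits()] (columns `cum_time`, `cum_distance_km`, `speed_mps`,
#' `formation`).
#'
#' @param phases A `race_phases` tibble from [parse_splits()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_splits_csv <- function(phases, path) {
  out <- tibble::tibble(
    cum_time = format_hms(cumsum(phases$duration_s)),
    cum_distance_km = cumsum(phases$distance_m) / 1000,
    speed_mps = round(phases$speed_mps, 4),
    formation = phases$formation
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Energy spent by one runner during one race phase
#'
#' Phase energy is phase duration times the runner's mechanical power at
#' the phase speed, with the power taken from the drag curve for the
#' runner's (formation, position). A runner absent from the phase spends
#' nothing.
#'
#' @param phase A one-row `race_phases` tibble (or list) with `duration_s`,
#'   `speed_mps`, `formation`.
#' @param position Position label the runner occupies in the phase, or
#'   `NA`/`NULL` when the runner is absent.
#' @param mass Runner mass, kg.
#' @param catalog A `drag_catalog`.
#' @param params Optional [power_model_params()]; by default built from
#'   `mass` with the catalog's solo curve.
#' @return Energy, J.
#' @examples
#' ph <- parse_splits(berlin_splits(2018))[4, ]
#' phase_energy(ph, "MAIN", mass = 52)
#' @export
phase_energy <- function(phase, position, mass = 52,
                         catalog = default_catalog(), params = NULL) {
  if (is.null(position) || is.na(position)) return(0)
  params <- params %||%
    power_model_params(mass = mass,
                       solo_drag_curve = catalog_curve(catalog, "SOLO", "MAIN"))
  curve <- catalog_curve(catalog, phase$formation, position)
  phase$duration_s * runner_power(phase$speed_mps, params, curve)
}

check_exposure <- function(exposure, phases, roster) {
  exposure <- tibble::as_tibble(exposure)
  if (!all(c("phase", "runner", "position") %in% names(exposure))) {
    abort("exposure needs columns `phase`, `runner`, `position`.")
  }
  if (!all(exposure$phase %in% phases$phase)) {
    abort("exposure refers to phases absent from the split table.")
  }
  if (!all(exposure$runner %in% roster$name)) {
    abort("exposure refers to runners absent from the roster.")
  }
  exposure
}

#' Per-runner, per-phase race energy ledger
#'
#' Expands a split table, a roster and an exposure table (which runner
#' occupied which position in which phase) into the energy each runner
#' spent in each phase, the machinery behind published per-race energy
#' expenditure tables. Totals are available via [ledger_totals()] or
#' [glance()].
#'
#' @param phases A `race_phases` tibble from [parse_splits()].
#' @param roster A data frame with columns `name` and `mass_kg`.
#' @param exposure A data frame with columns `phase`, `runner`, `position`;
#'   phases a runner does not appear in cost that runner nothing.
#' @param catalog A `drag_catalog`.
#' @return A `race_ledger` tibble with one row per (runner, phase)
#'   appearance: `runner`, `phase`, `formation`, `position`, `duration_s`,
#'   `speed_mps`, `energy_J`.
#' @examples
#' ph <- parse_splits(berlin_splits(2018))
#' race_energy_ledger(ph, berlin_roster(2018), berlin_exposure(2018))
#' @export
race_energy_ledger <- function(phases, roster, exposure,
                               catalog = default_catalog()) {
  roster <- tibble::as_tibble(roster)
  if (!all(c("name", "mass_kg") %in% names(roster))) {
    abort("roster needs columns `name` and `mass_kg`.")
  }
  exposure <- check_exposure(exposure, phases, roster)
  solo_curve <- catalog_curve(catalog, "SOLO", "MAIN")
  params_by_runner <- purrr::map(
    setNames(roster$mass_kg, roster$name),
    function(m) power_model_params(mass = m, solo_drag_curve = solo_curve)
  )
  out <- exposure |>
    dplyr::inner_join(tibble::as_tibble(phases), by = "phase") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      energy_J = phase_energy(
        list(duration_s = .data$duration_s, speed_mps = .data$speed_mps,
             formation = .data$formation),
        .data$position,
        catalog = catalog,
        params = params_by_runner[[.data$runner]]
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select("runner", "phase", "formation", "position",
                  "duration_s", "speed_mps", "energy_J") |>
    dplyr::arrange(.data$runner, .data$phase)
  class(out) <- c("race_ledger", class(out))
  out
}

#' Total energy per runner
#'
#' @param ledger A `race_ledger` from [race_energy_ledger()].
#' @return A tibble with columns `runner` and `energy_J`, sorted by
#'   descending energy.
#' @export
ledger_totals <- function(ledger) {
  tibble::as_tibble(ledger) |>
    dplyr::summarise(energy_J = sum(.data$energy_J), .by = "runner") |>
    dplyr::arrange(dplyr::desc(.data$energy_J))
}

#' @export
tidy.race_ledger <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.race_ledger <- function(x, ...) {
  totals <- ledger_totals(x)
  tibble::tibble(
    n_runners = nrow(totals),
    n_phases = dplyr::n_distinct(x$phase),
    total_energy_J = sum(totals$energy_J)
  )
}

#' Energy budgets from an actual race
#'
#' The conserved quantities of the race-time optimization: each runner's
#' budget is exactly the energy that runner spent in the actual race, so a
#' projected race may redistribute effort but never demand more total
#' energy of anyone than history did.
#'
#' @inheritParams race_energy_ledger
#' @return A tibble with columns `runner`, `mass_kg`, `budget_J` and a
#'   `provenance` string.
#' @examples
#' ph <- parse_splits(berlin_splits(2018))
#' budgets_from_actual_race(ph, berlin_roster(2018), berlin_exposure(2018))
#' @export
budgets_from_actual_race <- function(phases, roster, exposure,
                                     catalog = default_catalog()) {
  ledger <- race_energy_ledger(phases, roster, exposure, catalog)
  tibble::as_tibble(roster) |>
    dplyr::left_join(ledger_totals(ledger), by = c(name = "runner")) |>
    dplyr::mutate(
      budget_J = dplyr::coalesce(.data$energy_J, 0),
      provenance = "recomputed from actual-race splits",
      energy_J = NULL
    ) |>
    dplyr::select("name", "mass_kg", "budget_J", "provenance") |>
    dplyr::rename(runner = "name")
}
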