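#' Run the full drafting-and-pacing analysis for one scenario
#'
#' Executes the whole pipeline in the canonical order: parse the split
#' table, build the per-runner energy ledger of the actual race, freeze
#' those energies as budgets, minimise the projected race time under
#' energy conservation, and (optionally) evaluate the cooperative pacer
#' swap. The returned report carries every intermediate table plus the
#' provenance of each drag curve and budget, so every number in it is
#' traceable to its inputs.
#'
#' @param config A named list (or path to a YAML/JSON file with the same
#'   structure) with elements:
#'   \describe{
#'     \item{splits}{data frame in the [parse_splits()] schema, or a CSV
#'       path.}
#'     \item{roster}{data frame with `name`, `mass_kg` (or CSV path).}
#'     \item{exposure}{data frame with `phase`, `runner`, `position` (or
#'       CSV path).}
#'     \item{catalog}{a `drag_catalog`, a catalog CSV path, or omitted for
#'       [default_catalog()].}
#'     \item{cooperative}{logical; also run the cooperative variant
#'       (default `TRUE`).}
#'     \item{settings}{an [optimizer_settings()]; optional.}
#'     \item{strategy}{a [strategy_config()]; optional.}
#'     \item{label}{free-text scenario name.}
#'   }
#' @param actual_finish_s Optional actual finish time, s; defaults to the
#'   parsed split total. The reported improvement is this minus the
#'   ceil-rounded optimized total.
#' @return A `pacedraft_report` list with elements `label`, `actual`
#'   (per-phase table and total), `ledger`, `budgets`, `outcome`,
#'   `optimal` (per-phase tibble), `improvement_s`, `splitting`,
#'   `cooperative` (delta and outcome, when requested) and
#'   `curve_provenance`.
#' @examples
#' report <- run_full_analysis(list(
#'   splits = berlin_splits(2022),
#'   roster = berlin_roster(2022),
#'   exposure = berlin_exposure(2022),
#'   label = "Berlin 2022"
#' ))
#' report$improvement_s
#' @export
run_full_analysis <- function(config, actual_finish_s = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_scenario_config(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a file path.")
  need <- c("splits", "roster", "exposure")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    abort(sprintf("scenario config is missing: %s.",
                  paste(missing, collapse = ", ")))
  }
  load_tbl <- function(x) {
    if (is.character(x) && length(x) == 1) {
      readr::read_csv(x, show_col_types = FALSE)
    } else {
      tibble::as_tibble(x)
    }
  }
  catalog <- config$catalog %||% default_catalog()
  if (is.character(catalog)) catalog <- read_catalog_csv(catalog)
  settings <- config$settings %||% optimizer_settings()
  strategy <- config$strategy %||% strategy_config()
  roster <- load_tbl(config$roster)
  exposure <- load_tbl(config$exposure)

  phases <- if (inherits(config$splits, "race_phases")) {
    config$splits
  } else if (is.character(config$splits)) {
    parse_splits(config$splits)
  } else {
    parse_splits(load_tbl(config$splits))
  }
  actual_total <- sum(phases$duration_s)
  actual_finish_s <- actual_finish_s %||% actual_total

  ledger <- race_energy_ledger(phases, roster, exposure, catalog)
  budgets <- budgets_from_actual_race(phases, roster, exposure, catalog)
  outcome <- optimize_strategy(budgets, catalog, strategy, settings)
  improvement <- actual_finish_s - outcome$total_time_ceil

  coop <- NULL
  if (isTRUE(config$cooperative %||% TRUE)) {
    strategy_coop <- strategy; strategy_coop$cooperative <- TRUE
    coop_opt <- optimize_strategy(budgets, catalog, strategy_coop, settings)
    coop <- list(
      outcome = coop_opt,
      delta_time_s = outcome$total_time - coop_opt$total_time
    )
  }
  provenance <- tibble::as_tibble(catalog)[, c("formation", "position",
                                               "provenance")]
  structure(
    list(
      label = config$label %||% "scenario",
      actual = list(phases = phases, total_time_s = actual_total,
                    finish_time_s = actual_finish_s),
      ledger = ledger,
      budgets = budgets,
      outcome = outcome,
      optimal = outcome$phases,
      improvement_s = improvement,
      splitting = splitting_diagnosis(outcome),
      cooperative = coop,
      curve_provenance = provenance
    ),
    class = "pacedraft_report"
  )
}

#' @export
print.pacedraft_report <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$label))
  cat(sprintf("actual finish:   %s (%d s)\n",
              format_hms(x$actual$finish_time_s), x$actual$finish_time_s))
  cat(sprintf("optimized:       %s (%d s on the clock, %.2f s raw)\n",
              format_hms(x$outcome$total_time_ceil),
              x$outcome$total_time_ceil, x$outcome$total_time))
  cat(sprintf("improvement:     %d s; splitting: %s (phase-3 deficit %.1f%%)\n",
              round(x$improvement_s), x$splitting$splitting,
              100 * x$splitting$phase3_deficit))
  if (!is.null(x$cooperative)) {
    cat(sprintf("cooperative:     additional %.2f s\n",
                x$cooperative$delta_time_s))
  }
  invisible(x)
}

#' Read a scenario configuration file
#'
#' YAML (or JSON, which YAML parses as a subset) scenario files carry the
#' same keys as the list accepted by [run_full_analysis()], with table
#' values given as CSV paths relative to the config file. Unknown keys are
#' rejected so typos fail loudly instead of silently falling back to
#' defaults.
#'
#' @param path Path to a YAML/JSON scenario file.
#' @return A named list suitable for [run_full_analysis()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("splits", "roster", "exposure", "catalog", "cooperative",
               "settings", "strategy", "label")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown scenario keys: %s.", paste(unknown, collapse = ", ")))
  }
  base <- dirname(path)
  for (key in c("splits", "roster", "exposure", "catalog")) {
    if (is.character(cfg[[key]]) && !file.exists(cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  if (is.list(cfg$settings)) {
    cfg$settings <- do.call(optimizer_settings, cfg$settings)
  }
  if (is.list(cfg$strategy)) cfg$strategy <- do.call(strategy_config, cfg$strategy)
  cfg
}

#' Write an analysis report to JSON
#'
#' Serialises a `pacedraft_report` to structured JSON mirroring the
#' published result tables: per-phase speeds/distances/times, raw and
#' ceil-rounded totals, per-runner energy ledger and budgets with
#' provenance, splitting diagnosis, and the cooperative delta when
#' present. Output is deterministic for identical inputs.
#'
#' @param report A `pacedraft_report` from [run_full_analysis()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    label = report$label,
    actual = list(
      total_time_s = report$actual$total_time_s,
      finish_time_s = report$actual$finish_time_s,
      phases = report$actual$phases
    ),
    ledger_totals = ledger_totals(report$ledger),
    budgets = report$budgets,
    optimal = list(
      phases = report$optimal,
      total_time_s = report$outcome$total_time,
      total_time_ceil_s = report$outcome$total_time_ceil,
      residual_J = report$outcome$residual_J,
      feasible = report$outcome$feasible
    ),
    improvement_s = report$improvement_s,
    splitting = report$splitting,
    cooperative = if (!is.null(report$cooperative)) {
      list(delta_time_s = report$cooperative$delta_time_s,
           total_time_s = report$cooperative$outcome$total_time)
    },
    curve_provenance = report$curve_provenance
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Convenience wrapper: full analysis of one Berlin marathon
#'
#' Assembles the shipped split, roster and exposure transcriptions for the
#' requested year and runs [run_full_analysis()] on them with the default
#' catalog.
#'
#' @param year 2018 or 2022.
#' @param cooperative Also evaluate the cooperative pacer swap.
#' @param settings An [optimizer_settings()].
#' @param catalog A `drag_catalog`.
#' @return A `pacedraft_report`.
#' @examples
#' berlin_analysis(2022)
#' @export
berlin_analysis <- function(year, cooperative = TRUE,
                            settings = optimizer_settings(),
                            catalog = default_catalog()) {
  run_full_analysis(
    list(
      splits = berlin_splits(year),
      roster = berlin_roster(year),
      exposure = berlin_exposure(year),
      catalog = catalog,
      cooperative = cooperative,
      settings = settings,
      label = sprintf("Berlin %d marathon", as.integer(year))
    ),
    actual_finish_s = berlin_finish_time(year)
  )
}
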