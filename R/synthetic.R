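#' Specification for synthetic pipeline inputs
#'
#' Controls the synthetic-data generator that emulates everything the
#' pipeline consumes: drag-sample tables with the quadratic drag-speed
#' structure the analysis assumes, formation catalogs, rosters and race
#' split tables. Drag reductions are drawn from the range spanned by the
#' published formations (19% for a single laterally offset pacer up to 74%
#' for the five-pacer inverted arrow); optional Gaussian noise on the drag
#' samples emulates CFD fit residuals. Noise is never applied to the
#' power-model constants, which the analysis treats as exact.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of it.
#' @param n_formations Number of paced formations to generate (in addition
#'   to the solo reference).
#' @param reduction_range Range the main runner's drag reduction is drawn
#'   from, fractions in [0, 0.95).
#' @param noise_sd Standard deviation of Gaussian noise added to each drag
#'   sample, N.
#' @param speed_grid The four sampling speeds, m/s, strictly increasing.
#' @param roster_size Number of runners (one main runner plus pacers).
#' @param n_phases Number of phases in generated race fixtures (3 or 4).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_formations = 4,
                           reduction_range = c(0.19, 0.74),
                           noise_sd = 0,
                           speed_grid = cfd_speed_grid,
                           roster_size = 3,
                           n_phases = 4) {
  stopifnot(
    length(reduction_range) == 2,
    all(reduction_range >= 0), all(reduction_range < 0.95),
    noise_sd >= 0,
    length(speed_grid) == 4, all(diff(speed_grid) > 0),
    roster_size >= 3, n_phases %in% c(3, 4)
  )
  structure(
    list(seed = as.integer(seed), n_formations = as.integer(n_formations),
         reduction_range = reduction_range, noise_sd = noise_sd,
         speed_grid = as.numeric(speed_grid),
         roster_size = as.integer(roster_size),
         n_phases = as.integer(n_phases)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic formation catalog
#'
#' For each generated formation the main runner's curve is the solo
#' polynomial scaled by one minus a drawn reduction, the lead pacer sits
#' just below solo drag, and a sheltered trailing pacer position gets an
#' intermediate reduction; drag samples are emitted on the four-speed grid
#' with optional Gaussian noise and the catalog is rebuilt from those
#' samples with [fit_drag_curve()], exactly as a CFD table would be. With
#' zero noise the fit recovers the scaled polynomials to round-off.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `catalog` (a `drag_catalog`) and `samples`
#'   (a tibble of the emitted drag samples: `formation`, `position`,
#'   `reduction`, `v`, `drag`).
#' @examples
#' generate_catalog(synthetic_spec(seed = 7))$catalog
#' @export
generate_catalog <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  solo <- solo_drag_curve()
  entries <- tibble::tibble(
    formation = "SOLO", position = "MAIN", reduction = 0
  )
  for (i in seq_len(spec$n_formations)) {
    f <- paste0("S", i)
    r_main <- runif(1, spec$reduction_range[1], spec$reduction_range[2])
    r_lead <- runif(1, 0.01, 0.05)
    r_trail <- runif(1, 0.35, 0.60)
    entries <- dplyr::bind_rows(entries, tibble::tibble(
      formation = f,
      position = c("MAIN", "P1", "P2"),
      reduction = c(r_main, r_lead, r_trail)
    ))
  }
  samples <- entries |>
    tidyr::expand_grid(v = spec$speed_grid) |>
    dplyr::mutate(
      drag = (1 - .data$reduction) * drag_quadratic(solo, .data$v) +
        rnorm(dplyr::n(), 0, spec$noise_sd)
    )
  config <- samples |>
    dplyr::group_by(.data$formation, .data$position) |>
    dplyr::summarise(
      v1 = .data$v[1], v2 = .data$v[2], v3 = .data$v[3], v4 = .data$v[4],
      d1 = .data$drag[1], d2 = .data$drag[2], d3 = .data$drag[3],
      d4 = .data$drag[4],
      .groups = "drop"
    ) |>
    dplyr::mutate(provenance = "synthetic")
  list(catalog = build_catalog(config), samples = samples)
}

#' Generate a synthetic race fixture (splits and roster)
#'
#' Random mode emits a plausible paced marathon: 3-4 phases whose
#' formations shrink as pacers drop out (three pacers, then fewer, then
#' solo), phase speeds in [5.2, 6.0] m/s, integer-second durations and a
#' cumulative distance ending exactly at the marathon distance, so the
#' result always parses cleanly with [parse_splits()]. With `paper_mode`
#' set to a year, the shipped transcription of that year's Berlin marathon
#' is returned instead, byte-identical to the fixtures under
#' `inst/extdata/`.
#'
#' @param spec A [synthetic_spec()].
#' @param paper_mode `NULL`, 2018 or 2022.
#' @return A list with elements `splits` (cumulative schema, see
#'   [parse_splits()]), `roster` and `exposure`.
#' @examples
#' fx <- generate_race_fixture(synthetic_spec(seed = 3))
#' parse_splits(fx$splits)
#' @export
generate_race_fixture <- function(spec = synthetic_spec(), paper_mode = NULL) {
  if (!is.null(paper_mode)) {
    year <- as.integer(paper_mode)
    return(list(
      splits = berlin_splits(year),
      roster = berlin_roster(year),
      exposure = berlin_exposure(year)
    ))
  }
  set.seed(spec$seed + 1L)
  n <- spec$n_phases
  formations <- if (n == 4) c("F3", "F2", "F1", "SOLO") else c("F3", "F1", "SOLO")
  # phase distance shares: long paced opening, substantial solo finale
  w <- runif(n, 0.5, 1.5); w <- w / sum(w)
  dist <- w * marathon_distance_m
  speed <- runif(n, 5.21, 5.99) # margin keeps speeds in [5.2, 6] after rounding
  dur <- round(dist / speed)
  dist <- dur * speed # keep speeds exact after rounding durations
  dist <- dist * marathon_distance_m / sum(dist)
  speed <- dist / dur
  roster <- tibble::tibble(
    name = c("Main", paste0("Pacer", seq_len(spec$roster_size - 1))),
    role = c("main", rep("pacer", spec$roster_size - 1)),
    mass_kg = 52
  )
  pacer_names <- roster$name[-1]
  exposure <- purrr::map_dfr(seq_len(n), function(i) {
    pacers_in <- switch(formations[i],
      F3 = pacer_names[seq_len(min(3, length(pacer_names)))],
      F2 = pacer_names[seq_len(min(2, length(pacer_names)))],
      F1 = pacer_names[1],
      SOLO = character(0)
    )
    tibble::tibble(
      phase = i,
      runner = c("Main", pacers_in),
      position = c("MAIN", paste0("P", seq_along(pacers_in), recycle0 = TRUE))
    )
  })
  splits <- tibble::tibble(
    cum_time = format_hms(cumsum(dur)),
    cum_distance_km = cumsum(dist) / 1000,
    speed_mps = speed,
    formation = formations
  )
  list(splits = splits, roster = roster, exposure = exposure)
}

#' Generate a complete synthetic scenario
#'
#' Bundles a catalog, a race fixture and the optimizer configuration into
#' an end-to-end runnable scenario: the race fixture is priced with a
#' catalog that carries the standard formation keys (F1-F3 for the actual
#' race, F12/F4/SOLO for the projected one) with randomly drawn
#' reductions, and budgets are the energies spent in the synthetic actual
#' race, so the projected race is feasible by construction (pacers cannot
#' outlast the marathon distance at the minimum speed).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `catalog`, `splits`, `roster`, `exposure`,
#'   `budgets`, `config` and `settings`.
#' @examples
#' sc <- generate_scenario(synthetic_spec(seed = 11))
#' glance(optimize_strategy(sc$budgets, sc$catalog, sc$config, sc$settings))
#' @export
generate_scenario <- function(spec = synthetic_spec()) {
  set.seed(spec$seed + 2L)
  solo <- solo_drag_curve()
  mains <- tibble::tibble(
    formation = c("F1", "F2", "F3", "F4", "F12"),
    position = "MAIN",
    reduction = c(
      runif(1, 0.10, 0.25),  # one offset pacer
      runif(1, 0.35, 0.50),  # two pacers
      runif(1, 0.35, 0.50),  # three pacers
      runif(1, 0.45, 0.60),  # one pacer directly ahead
      runif(1, 0.55, 0.70)   # pacers fore and aft
    )
  )
  pacers <- tidyr::expand_grid(
    formation = c("F1", "F2", "F3", "F4", "F12"),
    position = c("P1", "P2", "P3")
  ) |>
    dplyr::mutate(reduction = runif(dplyr::n(), 0.01, 0.06))
  # the sheltered rear position of F12 draws a deeper reduction
  pacers$reduction[pacers$formation == "F12" & pacers$position == "P2"] <-
    runif(1, 0.35, 0.60)
  entries <- dplyr::bind_rows(
    tibble::tibble(formation = "SOLO", position = "MAIN", reduction = 0),
    mains, pacers
  )
  config_tbl <- entries |>
    dplyr::mutate(
      a = (1 - .data$reduction) * solo$a,
      b = (1 - .data$reduction) * solo$b,
      c = (1 - .data$reduction) * solo$c,
      provenance = "synthetic",
      reduction = NULL
    )
  catalog <- build_catalog(config_tbl)
  fx <- generate_race_fixture(spec)
  phases <- parse_splits(fx$splits)
  budgets <- budgets_from_actual_race(phases, fx$roster, fx$exposure, catalog)
  list(
    catalog = catalog,
    splits = fx$splits,
    roster = fx$roster,
    exposure = fx$exposure,
    budgets = budgets,
    config = strategy_config(),
    settings = optimizer_settings(seed = spec$seed)
  )
}
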