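#' Berlin marathon split tables
#'
#' Transcriptions of the per-formation running splits of the 2018 and 2022
#' Berlin marathons (both won by Eliud Kipchoge in world-record time), in
#' the cumulative CSV schema of [parse_splits()]. In 2018 Kipchoge ran
#' behind three pacers (Formation 3), then two (Formation 2), then one
#' (Formation 1), then alone; in 2022 the three-pacer phase was followed
#' directly by a single pacer and then a long solo stretch. The
#' `speed_mps` column carries the printed per-phase speeds used for
#' cross-checking.
#'
#' @param year 2018 or 2022.
#' @return A tibble with columns `cum_time`, `cum_distance_km`,
#'   `speed_mps`, `formation`. Pipe into [parse_splits()] for per-phase
#'   records.
#' @examples
#' parse_splits(berlin_splits(2022))
#' @export
berlin_splits <- function(year) {
  year <- as.integer(year)
  if (year == 2018L) {
    tibble::tribble(
      ~cum_time, ~cum_distance_km, ~speed_mps, ~formation,
      "00:41:17", 14.230, 5.744, "F3",
      "00:45:39", 15.690, 5.572, "F2",
      "01:14:23", 25.680, 5.794, "F1",
      "02:01:39", 42.195, 5.823, "SOLO"
    )
  } else if (year == 2022L) {
    tibble::tribble(
      ~cum_time, ~cum_distance_km, ~speed_mps, ~formation,
      "01:04:08", 22.590, 5.870, "F3",
      "01:10:08", 24.660, 5.750, "F1",
      "02:01:09", 42.195, 5.728, "SOLO"
    )
  } else {
    abort("`year` must be 2018 or 2022.")
  }
}

#' Berlin marathon rosters
#'
#' The main runner and the two pacers that matter to the energy analysis of
#' each race (the remaining pacers dropped out too early to shape the
#' projection). No pacer masses were published, so every runner defaults to
#' the main runner's 52 kg; mass is the natural knob to adjust when better
#' information is available.
#'
#' @param year 2018 or 2022.
#' @param mass_kg Body mass assigned to every runner, kg.
#' @return A tibble with columns `name`, `role` (`"main"`/`"pacer"`) and
#'   `mass_kg`.
#' @export
berlin_roster <- function(year, mass_kg = 52) {
  year <- as.integer(year)
  names <- switch(as.character(year),
    "2018" = c("Eliud Kipchoge", "Josphat Boit", "Sammy Kitwara"),
    "2022" = c("Eliud Kipchoge", "Jacob Kiplimo", "Isiah Koech"),
    abort("`year` must be 2018 or 2022.")
  )
  tibble::tibble(
    name = names,
    role = c("main", "pacer", "pacer"),
    mass_kg = mass_kg
  )
}

#' Berlin marathon pacer exposure
#'
#' Which runner occupied which position in which phase of the actual races,
#' following the dropout order implied by the shrinking formations: the
#' main runner is shielded (`MAIN`) in every paced phase; the stronger
#' pacer leads (`P1`) until his own dropout; the weaker pacer (`P2`) leaves
#' first. 2018: both named pacers through Formations 3 and 2, the stronger
#' alone in Formation 1, nobody in the solo phase. 2022: both in Formation
#' 3, the stronger alone in Formation 1.
#'
#' @param year 2018 or 2022.
#' @return A tibble with columns `phase`, `runner`, `position`, suitable
#'   for [race_energy_ledger()].
#' @export
berlin_exposure <- function(year) {
  year <- as.integer(year)
  if (year == 2018L) {
    tibble::tribble(
      ~phase, ~runner, ~position,
      1L, "Eliud Kipchoge", "MAIN",
      1L, "Josphat Boit", "P1",
      1L, "Sammy Kitwara", "P2",
      2L, "Eliud Kipchoge", "MAIN",
      2L, "Josphat Boit", "P1",
      2L, "Sammy Kitwara", "P2",
      3L, "Eliud Kipchoge", "MAIN",
      3L, "Josphat Boit", "P1",
      4L, "Eliud Kipchoge", "MAIN"
    )
  } else if (year == 2022L) {
    tibble::tribble(
      ~phase, ~runner, ~position,
      1L, "Eliud Kipchoge", "MAIN",
      1L, "Jacob Kiplimo", "P1",
      1L, "Isiah Koech", "P2",
      2L, "Eliud Kipchoge", "MAIN",
      2L, "Jacob Kiplimo", "P1",
      3L, "Eliud Kipchoge", "MAIN"
    )
  } else {
    abort("`year` must be 2018 or 2022.")
  }
}

#' Published per-runner race energies
#'
#' The per-runner total energy expenditures published for the two races,
#' in joules. The absolute values carry an unexplained uniform scale
#' factor of roughly 1.08 relative to what the power model yields on the
#' printed splits with 52 kg runners, so the package checks orderings and
#' ratios against this table, never absolute equality, and recomputes
#' budgets self-consistently for optimization.
#'
#' @param year 2018 or 2022.
#' @return A tibble with columns `runner` and `published_energy_J`.
#' @export
berlin_published_energies <- function(year) {
  year <- as.integer(year)
  switch(as.character(year),
    "2018" = tibble::tibble(
      runner = c("Eliud Kipchoge", "Josphat Boit", "Sammy Kitwara"),
      published_energy_J = c(9.1535e6, 5.6024e6, 3.424e6)
    ),
    "2022" = tibble::tibble(
      runner = c("Eliud Kipchoge", "Jacob Kiplimo", "Isiah Koech"),
      published_energy_J = c(9.1546e6, 5.4148e6, 4.9674e6)
    ),
    abort("`year` must be 2018 or 2022.")
  )
}

#' Actual finish times of the analysed races
#'
#' @param year 2018 or 2022.
#' @return Finish time in seconds (7299 s for 2018, 7269 s for 2022).
#' @export
berlin_finish_time <- function(year) {
  switch(as.character(as.integer(year)),
    "2018" = 7299,
    "2022" = 7269,
    abort("`year` must be 2018 or 2022.")
  )
}
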