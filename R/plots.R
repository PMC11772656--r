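#' Plot drag-versus-speed curves of a catalog
#'
#' One line per (formation, position) entry over the evaluation window,
#' the standard visual check that every curve is positive, increasing and
#' sensibly ordered relative to the solo reference.
#'
#' @param object A `drag_catalog`.
#' @param v_range Speed window to draw, m/s.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(default_catalog())
#' @export
autoplot.drag_catalog <- function(object, v_range = c(5, 6), ...) {
  grid <- tibble::as_tibble(object) |>
    dplyr::mutate(entry = paste(.data$formation, .data$position, sep = "/")) |>
    tidyr::expand_grid(v = seq(v_range[1], v_range[2], length.out = 50)) |>
    dplyr::mutate(drag_N = .data$a * .data$v^2 + .data$b * .data$v + .data$c)
  ggplot2::ggplot(grid, ggplot2::aes(.data$v, .data$drag_N,
                                     colour = .data$entry)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "running speed (m/s)", y = "drag force (N)",
      colour = "formation/position",
      title = "Formation drag curves"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the pacing profile of a projected race
#'
#' Step plot of speed against cumulative distance for the three phases,
#' making the splitting strategy visible at a glance.
#'
#' @param object A `race_outcome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.race_outcome <- function(object, ...) {
  ph <- object$phases
  steps <- tibble::tibble(
    distance_km = c(0, cumsum(ph$distance_m)) / 1000,
    speed_mps = c(ph$speed_mps, ph$speed_mps[3])
  )
  ggplot2::ggplot(steps, ggplot2::aes(.data$distance_km, .data$speed_mps)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "distance (km)", y = "speed (m/s)",
      title = sprintf("Projected pacing profile (total %.1f s)",
                      object$total_time)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-runner, per-phase energy expenditure
#'
#' Stacked bars of the energy each runner spent in each phase of an actual
#' race, the graphical counterpart of the energy ledger.
#'
#' @param ledger A `race_ledger` from [race_energy_ledger()].
#' @return A ggplot object.
#' @export
plot_energy_ledger <- function(ledger) {
  ggplot2::ggplot(
    tibble::as_tibble(ledger),
    ggplot2::aes(.data$runner, .data$energy_J / 1e6,
                 fill = factor(.data$phase))
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "energy (MJ)", fill = "phase",
                  title = "Race energy ledger") +
    ggplot2::theme_minimal()
}
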