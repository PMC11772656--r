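#' Quadratic drag-versus-speed curve
#'
#' Drag on a runner in a given formation and position is represented as a
#' quadratic in running speed, \eqn{F_D(v) = a v^2 + b v + c} (N), fitted
#' through drag samples on the four-speed grid [cfd_speed_grid]. The curve
#' must be positive throughout the optimizer's speed window [5, 6] m/s.
#'
#' @param a,b,c Quadratic coefficients (N s^2/m^2, N s/m, N).
#' @param formation Formation identifier, e.g. `"SOLO"`, `"F1"` ... `"F12"`.
#' @param position Position label within the formation: `"MAIN"` for the
#'   shielded runner, `"P1"` ... `"P6"` for pacers.
#' @param fit_speed_range Speed range (m/s) over which the curve was
#'   fitted; evaluation outside it triggers an extrapolation warning.
#' @param provenance Free-text origin of the coefficients (e.g.
#'   `"embedded solo polynomial"`, `"printed target-pace reduction"`,
#'   `"synthetic"`).
#' @return An object of class `drag_curve`.
#' @examples
#' solo <- solo_drag_curve()
#' evaluate_drag(solo, 5.86)
#' @export
drag_curve <- function(a, b, c, formation = "SOLO", position = "MAIN",
                       fit_speed_range = range(cfd_speed_grid),
                       provenance = "coefficients") {
  coefs <- c(a = a, b = b, c = c)
  if (any(!is.finite(coefs))) abort("drag-curve coefficients must be finite.")
  curve <- structure(
    list(
      a = a, b = b, c = c,
      formation = as.character(formation),
      position = as.character(position),
      fit_speed_range = as.numeric(fit_speed_range),
      provenance = provenance
    ),
    class = "drag_curve"
  )
  vv <- seq(5, 6, length.out = 41)
  if (any(drag_quadratic(curve, vv) <= 0)) {
    abort(sprintf(
      "nonphysical drag curve (%s/%s): F_D(v) not positive on [5, 6] m/s.",
      curve$formation, curve$position
    ))
  }
  curve
}

#' The unshielded runner's drag curve
#'
#' The quadratic drag polynomial for a solo elite runner,
#' \eqn{F_D(v) = 0.493 v^2 - 3.256 v + 7.878} N, obtained from CFD drag
#' samples on the four-speed grid. At the target pace of 5.86 m/s it gives
#' 5.73 N. It is both the reference every drag reduction is quoted against
#' and the aerodynamic term embedded in the running-power decomposition.
#'
#' @return A [drag_curve()] for `SOLO`/`MAIN`.
#' @export
solo_drag_curve <- function() {
  drag_curve(0.493, -3.256, 7.878,
    formation = "SOLO", position = "MAIN",
    provenance = "embedded solo polynomial"
  )
}

# raw quadratic, no range policy (used for power decomposition identities)
drag_quadratic <- function(curve, v) {
  curve$a * v^2 + curve$b * v + curve$c
}

#' @export
print.drag_curve <- function(x, ...) {
  cat(sprintf(
    "<drag_curve %s/%s> F_D(v) = %.4g v^2 + %.4g v + %.4g N  [fit %.3f-%.3f m/s]\n",
    x$formation, x$position, x$a, x$b, x$c,
    x$fit_speed_range[1], x$fit_speed_range[2]
  ))
  invisible(x)
}

#' Fit a quadratic drag curve through drag samples
#'
#' Least-squares quadratic fit of drag force against speed. With the usual
#' four samples and three coefficients the fit smooths CFD noise; when the
#' samples already lie on a single quadratic it interpolates them exactly.
#'
#' @param samples A data frame with columns `v` (speed, m/s, positive) and
#'   `drag` (force, N, positive); at least three distinct speeds.
#' @param formation,position Labels stored on the resulting curve.
#' @param provenance Provenance string stored on the curve.
#' @return A [drag_curve()] whose `fit_speed_range` is the sample range.
#' @examples
#' s <- tibble::tibble(v = cfd_speed_grid,
#'                     drag = 0.493 * v^2 - 3.256 * v + 7.878)
#' fit_drag_curve(s)
#' @export
fit_drag_curve <- function(samples, formation = "SOLO", position = "MAIN",
                           provenance = "fitted from samples") {
  samples <- tibble::as_tibble(samples)
  if (!all(c("v", "drag") %in% names(samples))) {
    abort("`samples` needs columns `v` and `drag`.")
  }
  if (any(samples$v <= 0) || any(samples$drag <= 0)) {
    abort("drag samples must have positive speed and positive drag.")
  }
  if (length(unique(samples$v)) < 3) {
    abort("need at least 3 samples with distinct speeds to fit a quadratic.")
  }
  fit <- lm(drag ~ I(v^2) + v, data = samples)
  cf <- coef(fit)
  drag_curve(
    a = unname(cf["I(v^2)"]), b = unname(cf["v"]), c = unname(cf["(Intercept)"]),
    formation = formation, position = position,
    fit_speed_range = range(samples$v), provenance = provenance
  )
}

#' Evaluate a drag curve
#'
#' Drag force at speed `v`. Speeds outside the curve's fitted range are
#' extrapolated with a warning; the quadratic form is only trusted near the
#' sampled speeds.
#'
#' @param curve A [drag_curve()].
#' @param v Speed, m/s, positive. Vectorised.
#' @param warn_extrapolation Emit a warning when `v` falls outside the
#'   curve's `fit_speed_range`.
#' @return Drag force, N.
#' @examples
#' evaluate_drag(solo_drag_curve(), 5.86)
#' @export
evaluate_drag <- function(curve, v, warn_extrapolation = TRUE) {
  if (any(!is.finite(v)) || any(v <= 0)) abort("`v` must be positive.")
  rng <- curve$fit_speed_range
  if (warn_extrapolation && any(v < rng[1] | v > rng[2])) {
    warn(sprintf(
      "extrapolating drag curve %s/%s outside its fit range [%.3f, %.3f] m/s.",
      curve$formation, curve$position, rng[1], rng[2]
    ))
  }
  drag_quadratic(curve, v)
}

#' Drag reduction of one curve relative to a reference
#'
#' Fractional drag reduction \eqn{1 - F_D(v) / F_{D,ref}(v)} at speed `v`,
#' the quantity usually quoted when comparing a drafting position against
#' the unshielded runner.
#'
#' @param curve,reference [drag_curve()] objects.
#' @param v Speed, m/s (default: the target pace).
#' @return Fraction; positive when `curve` has less drag than `reference`.
#' @examples
#' cat12 <- default_catalog()
#' drag_reduction(catalog_curve(cat12, "F12", "MAIN"), solo_drag_curve())
#' @export
drag_reduction <- function(curve, reference, v = target_pace_mps) {
  fd_ref <- drag_quadratic(reference, v)
  if (any(fd_ref <= 0)) abort("reference drag must be positive at `v`.")
  1 - drag_quadratic(curve, v) / fd_ref
}

#' Dimensionless drag coefficient
#'
#' \eqn{C_d = F_D / (\tfrac12 \rho v^2 A)}: drag normalised by dynamic
#' pressure times projected frontal area, used to compare drag results
#' across studies with different runner sizes, speeds and air conditions.
#'
#' @param F_D Drag force, N.
#' @param v Speed, m/s, positive.
#' @param air An [air_properties()] object.
#' @param geom A [runner_geometry()] object.
#' @return Dimensionless drag coefficient.
#' @examples
#' drag_coefficient(5.73, 5.86)
#' @export
drag_coefficient <- function(F_D, v, air = air_properties(),
                             geom = runner_geometry()) {
  if (any(v <= 0)) abort("`v` must be positive.")
  q <- 0.5 * air$density * v^2 * geom$frontal_area
  if (any(q <= 0)) abort("dynamic pressure times area must be positive.")
  F_D / q
}

#' @rdname drag_curve
#' @param x A `drag_curve`.
#' @param ... Unused.
#' @export
tidy.drag_curve <- function(x, ...) {
  tibble::tibble(
    term = c("v^2", "v", "(Intercept)"),
    estimate = c(x$a, x$b, x$c)
  )
}

#' @rdname drag_curve
#' @export
glance.drag_curve <- function(x, ...) {
  tibble::tibble(
    formation = x$formation,
    position = x$position,
    drag_at_target_N = drag_quadratic(x, target_pace_mps),
    reduction_vs_solo = drag_reduction(x, solo_drag_curve()),
    fit_lo = x$fit_speed_range[1],
    fit_hi = x$fit_speed_range[2],
    provenance = x$provenance
  )
}
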