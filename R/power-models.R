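#' Running-power model parameters
#'
#' Bundles the constants of the mechanical running-power model. Total
#' mechanical power is `mass * v * (cost_quadratic * v^2 + cost_constant)`:
#' the cost of running \eqn{C_r = 0.018 v^2 + 3.2833} J/(kg m), measured on
#' elite Kenyan marathon runners on a track, times speed and body mass.
#' Because the track measurements include the work done against air
#' resistance, the solo drag curve is carried along so that the aerodynamic
#' share can be stripped out again (see [nonaero_power()]).
#'
#' @param mass Body mass in kg. The default, 52 kg, is Eliud Kipchoge's
#'   listed mass, for whom the published cost-of-running constants were
#'   scaled.
#' @param cost_quadratic Coefficient of `v^2` in the cost of running,
#'   J s^2/(kg m^3).
#' @param cost_constant Constant cost-of-running term, J/(kg m).
#' @param solo_drag_curve A [drag_curve()] describing the drag on an
#'   unshielded runner; used to separate aerodynamic from non-aerodynamic
#'   power.
#' @return An object of class `power_model_params`.
#' @examples
#' p <- power_model_params()
#' total_power_tam(5.86, p)
#' @export
power_model_params <- function(mass = 52,
                               cost_quadratic = 0.018,
                               cost_constant = 3.2833,
                               solo_drag_curve = pacedraft::solo_drag_curve()) {
  stopifnot(is.numeric(mass), length(mass) == 1, is.finite(mass))
  if (mass <= 0) abort("`mass` must be positive.")
  if (cost_constant <= 0) abort("`cost_constant` must be positive.")
  if (cost_quadratic < 0) abort("`cost_quadratic` must be non-negative.")
  if (!inherits(solo_drag_curve, "drag_curve")) {
    abort("`solo_drag_curve` must be a drag_curve object.")
  }
  structure(
    list(
      mass = mass,
      cost_quadratic = cost_quadratic,
      cost_constant = cost_constant,
      solo_drag_curve = solo_drag_curve
    ),
    class = "power_model_params"
  )
}

#' @export
print.power_model_params <- function(x, ...) {
  cat(sprintf(
    "<power_model_params> mass %.1f kg, Cr(v) = %.4g v^2 + %.4f J/(kg m)\n",
    x$mass, x$cost_quadratic, x$cost_constant
  ))
  invisible(x)
}

#' Ambient air properties
#'
#' Air density is derived from ambient pressure and temperature through the
#' ideal-gas law (specific gas constant 287.058 J/(kg K)). The defaults,
#' 101325 Pa at 20 degrees C, give the 1.204 kg/m^3 used when quoting drag
#' coefficients.
#'
#' @param pressure Ambient pressure, Pa.
#' @param temperature Air temperature, degrees Celsius.
#' @return An object of class `air_properties` with fields `pressure`,
#'   `temperature` and `density`.
#' @export
air_properties <- function(pressure = 101325, temperature = 20) {
  if (pressure <= 0) abort("`pressure` must be positive.")
  if (temperature <= -273.15) abort("`temperature` must be above absolute zero.")
  density <- pressure / (287.058 * (temperature + 273.15))
  structure(
    list(pressure = pressure, temperature = temperature, density = density),
    class = "air_properties"
  )
}

#' Runner frontal geometry
#'
#' Projected frontal area and height of the runner, needed only to convert
#' drag forces into dimensionless drag coefficients. The default area,
#' 0.4264 m^2, is the area implied by a 5.73 N drag at 5.86 m/s with a drag
#' coefficient of 0.65 in standard air; the default height matches Eliud
#' Kipchoge's 1.67 m.
#'
#' @param frontal_area Projected frontal area, m^2.
#' @param height Runner height, m.
#' @return An object of class `runner_geometry`.
#' @export
runner_geometry <- function(frontal_area = 0.4264, height = 1.67) {
  if (frontal_area <= 0) abort("`frontal_area` must be positive.")
  if (height <= 0) abort("`height` must be positive.")
  structure(
    list(frontal_area = frontal_area, height = height),
    class = "runner_geometry"
  )
}

check_speed <- function(u, arg = "u") {
  if (!is.numeric(u) || any(!is.finite(u))) {
    abort(sprintf("`%s` must be finite numeric.", arg))
  }
  if (any(u < 0)) abort(sprintf("`%s` must be non-negative.", arg))
  invisible(u)
}

#' Specific running power, force-platform model
#'
#' Early empirical model relating running speed to mass-specific mechanical
#' power, obtained from force-platform experiments:
#' \eqn{P = 0.436 u^{2.01}} with `u` in m/s and the result in W/kg.
#'
#' @param u Running speed, m/s. Vectorised.
#' @return Specific power, W/kg.
#' @examples
#' power_fukunaga(c(0, 1, 5.86))
#' @export
power_fukunaga <- function(u) {
  check_speed(u)
  0.436 * u^2.01
}

#' Specific running power, internal-plus-external work model
#'
#' Model of mass-specific running power that accounts for both the external
#' work and the internal work of accelerating the limbs relative to the
#' trunk: \eqn{P = 9.42 + 4.73 u + 0.266 u^{1.993}} with `u` in km/h and the
#' result in cal/(min kg). The non-zero intercept is the measured cost of
#' sustaining motion at vanishing speed and is deliberately kept as
#' published.
#'
#' @param u Running speed, km/h. Vectorised.
#' @return Specific power, cal/(min kg).
#' @examples
#' power_cavagna(21.096) # 5.86 m/s
#' @export
power_cavagna <- function(u) {
  check_speed(u)
  9.42 + 4.73 * u + 0.266 * u^1.993
}

#' Total mechanical running power
#'
#' Total mechanical power of a runner of the given mass at speed `v`:
#' mass times speed times cost of running,
#' `mass * v * (cost_quadratic * v^2 + cost_constant)` in W. With the
#' default parameters this is \eqn{52 v (0.018 v^2 + 3.2833)}, the
#' track-measured model for elite Kenyan marathon runners; it includes the
#' aerodynamic share of the work (see [nonaero_power()]).
#'
#' @param v Running speed, m/s. Vectorised.
#' @param params A [power_model_params()] object.
#' @return Power, W.
#' @examples
#' total_power_tam(5.86)
#' @export
total_power_tam <- function(v, params = power_model_params()) {
  check_speed(v, "v")
  params$mass * v * (params$cost_quadratic * v^2 + params$cost_constant)
}

#' Aerodynamic running power
#'
#' Power spent against air resistance: drag force times speed,
#' \eqn{W_a = F_D(v) \cdot v}, with the drag force taken from a formation-
#' and position-specific [drag_curve()].
#'
#' @param curve A [drag_curve()].
#' @param v Running speed, m/s. Vectorised.
#' @return Power, W.
#' @examples
#' aero_power(solo_drag_curve(), 5.86)
#' @export
aero_power <- function(curve, v) {
  check_speed(v, "v")
  drag_quadratic(curve, v) * v
}

#' Non-aerodynamic running power
#'
#' The share of total mechanical power not spent against air resistance:
#' [total_power_tam()] minus the aerodynamic power of the *unshielded*
#' runner. Because the cost-of-running constants were measured on a track
#' (drag included), stripping the solo aerodynamic term recovers the
#' drag-free mechanical power; a formation-specific aerodynamic term can
#' then be added back (see [runner_power()]).
#'
#' @inheritParams total_power_tam
#' @return Power, W.
#' @examples
#' nonaero_power(5.86)
#' @export
nonaero_power <- function(v, params = power_model_params()) {
  total_power_tam(v, params) - aero_power(params$solo_drag_curve, v)
}

#' Running power in a drafting formation
#'
#' Mechanical power of a runner occupying a given position in a formation:
#' non-aerodynamic power plus the aerodynamic power for that position's
#' drag curve. With the solo curve this reproduces [total_power_tam()]
#' exactly; with any curve of lower drag, drafting reduces the required
#' power.
#'
#' @inheritParams total_power_tam
#' @param curve The [drag_curve()] for the runner's formation and position.
#' @return Power, W.
#' @examples
#' runner_power(5.86, curve = solo_drag_curve())
#' @export
runner_power <- function(v, params = power_model_params(),
                         curve = params$solo_drag_curve) {
  nonaero_power(v, params) + aero_power(curve, v)
}

#' Compare the two specific-power models on a speed grid
#'
#' Evaluates the force-platform model ([power_fukunaga()]) and the
#' internal-plus-external work model ([power_cavagna()]) on a common speed
#' grid, converting the latter from cal/(min kg) to W/kg, and reports the
#' largest relative difference and where it occurs. The calorie-to-joule
#' factor is configurable because published comparisons do not state which
#' calorie convention they used; the default is the thermochemical calorie.
#'
#' @param v_lo,v_hi Speed range, m/s; `v_lo <= v_hi`.
#' @param n_points Number of grid points (>= 1; 1 requires `v_lo == v_hi`).
#' @param calorie_joules Joules per calorie used for the unit conversion.
#' @return A one-row tibble with columns `max_rel_diff` (fraction),
#'   `speed_at_max` (m/s), `n_points` and `calorie_joules`. The full
#'   evaluation grid is attached as attribute `"grid"` (a tibble with the
#'   two powers in W/kg and the signed relative difference).
#' @examples
#' compare_power_models(5.238, 5.950, 100)
#' @export
compare_power_models <- function(v_lo, v_hi, n_points = 100,
                                 calorie_joules = 4.184) {
  if (!is.finite(v_lo) || !is.finite(v_hi) || v_lo <= 0 || v_hi < v_lo) {
    abort("need 0 < v_lo <= v_hi.")
  }
  if (n_points < 1 || (n_points == 1 && v_hi != v_lo)) {
    abort("`n_points` must be >= 2, or 1 with v_lo == v_hi.")
  }
  v <- if (n_points == 1) v_lo else seq(v_lo, v_hi, length.out = n_points)
  p1 <- power_fukunaga(v)                                   # W/kg
  p2 <- power_cavagna(v * 3.6) * calorie_joules / 60        # cal/(min kg) -> W/kg
  rel <- (p2 - p1) / p1
  grid <- tibble::tibble(speed_mps = v, p_fukunaga = p1, p_cavagna = p2,
                         rel_diff = rel)
  i <- which.max(abs(rel))
  out <- tibble::tibble(
    max_rel_diff = abs(rel[i]),
    speed_at_max = v[i],
    n_points = as.integer(n_points),
    calorie_joules = calorie_joules
  )
  attr(out, "grid") <- grid
  out
}
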