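# Constitutive laws for the shunt element and porous outlet zones.

shunt_linear_coefficient <- function(spec, blood) {
  # Poiseuille: dP = 128 mu L / (pi d^4) * Q
  128 * blood$viscosity * spec$length / (pi * spec$diameter^4)
}

shunt_quadratic_coefficient <- function(spec, blood) {
  # minor loss: dP = K rho/2 (Q/A)^2 sign(Q) = b Q |Q|
  area <- pi * spec$diameter^2 / 4
  spec$minor_loss_coefficient * blood$density / (2 * area^2)
}

#' Pressure drop across the shunt graft
#'
#' The lumped pressure--flow law of the cylindrical shunt:
#' \deqn{\Delta P = \frac{128 \mu L}{\pi d^4} Q
#'   + K \frac{\rho}{2} \left(\frac{Q}{A}\right)^2 \mathrm{sign}(Q),}
#' a Poiseuille term for fully developed laminar flow in the graft plus a
#' quadratic minor loss (coefficient \eqn{K}) for the anastomoses, with
#' \eqn{A = \pi d^2/4}. The law is odd and strictly increasing in \eqn{Q}.
#'
#' @param spec a [shunt_spec()].
#' @param flow volumetric flow through the shunt (m\eqn{^3}/s); may be
#'   negative (reversed flow) or a vector.
#' @param blood a [blood_properties()].
#' @return Pressure drop (Pa), same length as `flow`.
#' @export
#' @examples
#' sp <- shunt_spec(diameter = 0.004, minor_loss_coefficient = 0)
#' shunt_pressure_drop(sp, 1e-5, blood_properties())  # ~159.2 Pa, pure Poiseuille
shunt_pressure_drop <- function(spec, flow, blood) {
  if (!inherits(spec, "shunt_spec")) {
    abort_shuntr("invalid_spec", "`spec` must be a shunt_spec object")
  }
  if (!is.numeric(flow) || any(!is.finite(flow))) {
    abort_shuntr("invalid_argument", "`flow` must be finite numeric")
  }
  a <- shunt_linear_coefficient(spec, blood)
  b <- shunt_quadratic_coefficient(spec, blood)
  a * flow + b * flow * abs(flow)
}

# closed-form inverse of dp = a q + b q |q| (odd, monotone)
shunt_flow_from_dp <- function(dp, a, b) {
  s <- sign(dp)
  x <- abs(dp)
  if (b == 0) return(dp / a)
  s * (-a + sqrt(a * a + 4 * b * x)) / (2 * b)
}

#' Reynolds number of a tube flow
#'
#' \eqn{Re = \rho v d / \mu} with the mean velocity \eqn{v = Q/(\pi d^2/4)}.
#' Used as a diagnostic on the shunt: the lumped model reports the mean-flow
#' Reynolds number, which is far below local 3D values near the anastomosis.
#'
#' @param flow volumetric flow (m\eqn{^3}/s); vectorised.
#' @param diameter tube diameter (m).
#' @param blood a [blood_properties()].
#' @return Dimensionless Reynolds number (non-negative).
#' @export
#' @examples
#' reynolds_number(1.777e-5, 0.003, blood_properties())  # ~1.6e3
reynolds_number <- function(flow, diameter, blood) {
  check_positive(diameter, "diameter")
  area <- pi * diameter^2 / 4
  v <- abs(flow) / area
  blood$density * v * diameter / blood$viscosity
}

#' Convert a lumped outlet resistance to a porous-zone viscous coefficient
#'
#' Outlet resistances are realised in 3D CFD as porous zones; the isotropic
#' per-area viscous coefficient is
#' \deqn{X = \frac{R \cdot A}{\mu \cdot l},}
#' where \eqn{R} is the lumped resistance (pass SI Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}};
#' convert printed MPa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}} values with
#' [MPa_s_m3_to_SI()]), \eqn{A} the outlet area, \eqn{\mu} the blood
#' viscosity and \eqn{l} the porous-zone length.
#'
#' @param resistance lumped resistance (Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}).
#' @param area outlet area (m\eqn{^2}).
#' @param viscosity blood dynamic viscosity (Pa\eqn{\cdot}s).
#' @param length porous-zone length (m).
#' @return Viscous resistance coefficient \eqn{X} (m\eqn{^{-2}}).
#' @export
#' @examples
#' viscous_resistance(MPa_s_m3_to_SI(131), 1e-5, 0.005, 0.01)  # 2.62e7 m^-2
viscous_resistance <- function(resistance, area, viscosity, length) {
  check_positive(resistance, "resistance")
  check_positive(area, "area")
  check_positive(viscosity, "viscosity")
  check_positive(length, "length")
  resistance * area / (viscosity * length)
}

#' Recover a lumped resistance from a porous viscous coefficient
#'
#' Algebraic inverse of [viscous_resistance()]: \eqn{R = X \mu l / A}.
#'
#' @param x viscous coefficient (m\eqn{^{-2}}).
#' @inheritParams viscous_resistance
#' @return Lumped resistance (Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}).
#' @export
resistance_from_viscous <- function(x, area, viscosity, length) {
  check_positive(x, "x")
  check_positive(area, "area")
  check_positive(viscosity, "viscosity")
  check_positive(length, "length")
  x * viscosity * length / area
}
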