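#' Blood rheology for the Newtonian blood model
#'
#' Blood is treated as an incompressible Newtonian fluid. The defaults are the
#' values commonly used for pediatric shunt modelling: density
#' 1060 kg/m\eqn{^3} and dynamic viscosity 0.005 Pa\eqn{\cdot}s.
#'
#' @param density mass density \eqn{\rho} (kg/m\eqn{^3}).
#' @param viscosity dynamic viscosity \eqn{\mu} (Pa\eqn{\cdot}s).
#' @return A `blood_properties` object.
#' @export
#' @examples
#' blood_properties()
blood_properties <- function(density = 1060, viscosity = 0.005) {
  check_positive(density, "density")
  check_positive(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf("<blood_properties> rho = %g kg/m^3, mu = %g Pa.s\n",
              x$density, x$viscosity))
  invisible(x)
}

OUTLET_NAMES <- c("IA", "LCA", "LSA", "DAO", "LPA", "RPA")
SYSTEMIC_OUTLETS <- c("IA", "LCA", "LSA", "DAO")
PULMONARY_OUTLETS <- c("LPA", "RPA")

#' Outlet resistance boundary condition
#'
#' One downstream vascular bed, lumped into a linear resistance discharging to
#' the venous reference pressure. The `area` and `porous_length` describe the
#' outlet lumen and the porous zone used when the resistance is converted to a
#' per-area viscous coefficient (see [viscous_resistance()]).
#'
#' @param name one of `"IA"`, `"LCA"`, `"LSA"`, `"DAO"`, `"LPA"`, `"RPA"`
#'   (innominate, left carotid, left subclavian, descending aorta, left and
#'   right pulmonary artery).
#' @param resistance lumped resistance (Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}).
#'   Use [MPa_s_m3_to_SI()] for values quoted in MPa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}.
#' @param area outlet lumen cross-section (m\eqn{^2}).
#' @param porous_length porous-zone length \eqn{l} (m).
#' @return An `outlet_bc` object.
#' @export
outlet_bc <- function(name, resistance, area, porous_length = 0.01) {
  if (!is.character(name) || length(name) != 1L || !(name %in% OUTLET_NAMES)) {
    abort_shuntr("invalid_argument",
                 sprintf("outlet `name` must be one of: %s",
                         paste(OUTLET_NAMES, collapse = ", ")))
  }
  check_positive(resistance, "resistance")
  check_positive(area, "area")
  check_positive(porous_length, "porous_length")
  structure(list(name = name, resistance = resistance, area = area,
                 porous_length = porous_length),
            class = "outlet_bc")
}

#' Shunt geometry and loss model
#'
#' A cylindrical synthetic graft bridging the ascending aorta and the pulmonary
#' artery. Its pressure--flow law combines fully developed laminar (Poiseuille)
#' resistance with a quadratic minor loss representing the anastomoses
#' (see [shunt_pressure_drop()]).
#'
#' @param diameter inner diameter (m). Grid cases use 3--5 mm.
#' @param length graft length (m); default 20 mm, a typical central-shunt scale.
#' @param minor_loss_coefficient dimensionless loss coefficient K for the two
#'   anastomoses; default 1.5 (entrance plus tee-junction order of magnitude).
#' @return A `shunt_spec` object.
#' @export
shunt_spec <- function(diameter, length = 0.02, minor_loss_coefficient = 1.5) {
  check_positive(diameter, "diameter")
  check_positive(length, "length")
  check_nonnegative(minor_loss_coefficient, "minor_loss_coefficient")
  structure(list(diameter = diameter, length = length,
                 minor_loss_coefficient = minor_loss_coefficient),
            class = "shunt_spec")
}

#' Patient-level arterial network description
#'
#' Bundles everything patient-specific: blood rheology, the six outlet
#' boundary conditions, the shunt loss model (diameter is overridden per
#' case), inlet lumen areas, the left/right pulmonary asymmetry factor and the
#' venous reference pressure.
#'
#' @param blood a [blood_properties()] object.
#' @param outlets list of six [outlet_bc()] objects: exactly the four systemic
#'   outlets (IA, LCA, LSA, DAO) and the two pulmonary outlets (LPA, RPA).
#' @param shunt a [shunt_spec()] giving length and minor-loss coefficient (its
#'   diameter acts as a default, replaced by each case).
#' @param lpa_rpa_asymmetry multiplier applied to the LPA series resistance;
#'   1 gives a perfectly symmetric pulmonary split. Stands in for the 3D
#'   branching geometry the lumped model cannot represent.
#' @param aortic_root_area ascending-aorta inlet lumen area (m\eqn{^2}).
#' @param mpa_area main pulmonary artery inlet lumen area (m\eqn{^2}).
#' @param reference_pressure outlet/venous reference pressure (Pa); outlets
#'   discharge to this pressure. Default 0 (venous pressure neglected, which is
#'   consistent with resistances calibrated against mean arterial pressure).
#' @return A `patient_network` object.
#' @seealso [reference_patient()] for the printed-parameter reference patient.
#' @export
patient_network <- function(blood, outlets, shunt,
                            lpa_rpa_asymmetry = 1,
                            aortic_root_area = pi * (0.012 / 2)^2,
                            mpa_area = pi * (0.008 / 2)^2,
                            reference_pressure = 0) {
  if (!inherits(blood, "blood_properties")) {
    abort_shuntr("invalid_argument", "`blood` must be a blood_properties object")
  }
  if (!inherits(shunt, "shunt_spec")) {
    abort_shuntr("invalid_argument", "`shunt` must be a shunt_spec object")
  }
  if (!is.list(outlets) || !all(vapply(outlets, inherits, logical(1), "outlet_bc"))) {
    abort_shuntr("invalid_argument", "`outlets` must be a list of outlet_bc objects")
  }
  nm <- vapply(outlets, `[[`, character(1), "name")
  names(outlets) <- nm
  if (!setequal(nm, OUTLET_NAMES) || anyDuplicated(nm)) {
    abort_shuntr("invalid_argument",
                 "`outlets` must contain exactly IA, LCA, LSA, DAO, LPA, RPA")
  }
  check_positive(lpa_rpa_asymmetry, "lpa_rpa_asymmetry")
  check_positive(aortic_root_area, "aortic_root_area")
  check_positive(mpa_area, "mpa_area")
  if (!is.numeric(reference_pressure) || length(reference_pressure) != 1L ||
      !is.finite(reference_pressure)) {
    abort_shuntr("invalid_argument", "`reference_pressure` must be a finite number")
  }
  structure(list(blood = blood, outlets = outlets[OUTLET_NAMES], shunt = shunt,
                 lpa_rpa_asymmetry = lpa_rpa_asymmetry,
                 aortic_root_area = aortic_root_area, mpa_area = mpa_area,
                 reference_pressure = reference_pressure),
            class = "patient_network")
}

#' @export
print.patient_network <- function(x, ...) {
  r <- vapply(x$outlets, `[[`, numeric(1), "resistance")
  cat("<patient_network>\n")
  cat(sprintf("  outlet R (MPa.s.m-3): %s\n",
              paste(sprintf("%s=%.0f", names(r), SI_to_MPa_s_m3(r)), collapse = " ")))
  cat(sprintf("  shunt: L = %g mm, K = %g; LPA/RPA asymmetry = %g\n",
              x$shunt$length * 1e3, x$shunt$minor_loss_coefficient,
              x$lpa_rpa_asymmetry))
  invisible(x)
}

GRID_DIAMETERS_MM <- c(3, 3.5, 4, 4.5, 5)
GRID_ALPHAS <- c(0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30)

#' One point of the design grid
#'
#' A simulation case: shunt diameter, stenosis ratio \eqn{\alpha} and cardiac
#' output. \eqn{\alpha} is the fraction of cardiac output entering through the
#' native (stenosed) main pulmonary artery: \eqn{\alpha = Q_{MPA}/CO}, so
#' \eqn{\alpha = 0} is pulmonary atresia and larger \eqn{\alpha} is milder
#' stenosis.
#'
#' @param shunt_diameter shunt inner diameter (m).
#' @param alpha stenosis ratio in \eqn{[0, 1)}; the study grid uses
#'   0, 0.05, ..., 0.30.
#' @param cardiac_output cardiac output (m\eqn{^3}/s).
#' @return A `case_definition` object.
#' @export
case_definition <- function(shunt_diameter, alpha, cardiac_output) {
  check_positive(shunt_diameter, "shunt_diameter")
  check_positive(cardiac_output, "cardiac_output")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha >= 1) {
    abort_shuntr("invalid_case", "`alpha` must lie in [0, 1)")
  }
  structure(list(shunt_diameter = shunt_diameter, alpha = alpha,
                 cardiac_output = cardiac_output),
            class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("<case_definition> d = %g mm, alpha = %g%%, CO = %.3f L/min\n",
              x$shunt_diameter * 1e3, 100 * x$alpha,
              m3s_to_lmin(x$cardiac_output)))
  invisible(x)
}
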