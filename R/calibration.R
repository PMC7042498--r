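# Outlet resistance calibration against clinical pressure targets. The paper-
# grade procedure: pick systemic outlet resistances so that a prescribed
# systemic flow, distributed in physiological fractions, reproduces the
# clinical mean arterial pressure at the aortic node. Pulmonary downstream
# resistances are held fixed (PVR is not calibrated).

#' Clinical calibration targets
#'
#' @param systolic_pressure aortic systolic pressure (mmHg).
#' @param diastolic_pressure aortic diastolic pressure (mmHg).
#' @param target_flow_fractions named numeric vector of per-outlet fractions of
#'   systemic flow (names from IA, LCA, LSA, DAO), summing to 1.
#' @param pressure_tolerance acceptable relative mismatch between model and
#'   clinical mean arterial pressure (fraction; default 0.05).
#' @return A `clinical_targets` object.
#' @export
clinical_targets <- function(systolic_pressure, diastolic_pressure,
                             target_flow_fractions,
                             pressure_tolerance = 0.05) {
  check_positive(systolic_pressure, "systolic_pressure")
  check_positive(diastolic_pressure, "diastolic_pressure")
  if (systolic_pressure < diastolic_pressure) {
    abort_shuntr("invalid_argument", "systolic pressure must be >= diastolic pressure")
  }
  f <- target_flow_fractions
  if (is.null(names(f)) || !all(names(f) %in% SYSTEMIC_OUTLETS) || anyDuplicated(names(f))) {
    abort_shuntr("invalid_argument",
                 "flow fractions must be named with systemic outlets (IA, LCA, LSA, DAO)")
  }
  if (any(f <= 0) || any(f >= 1)) {
    abort_shuntr("invalid_argument", "flow fractions must lie in (0, 1)")
  }
  if (abs(sum(f) - 1) > 1e-12) {
    abort_shuntr("invalid_argument", "flow fractions must sum to 1 (within 1e-12)")
  }
  check_positive(pressure_tolerance, "pressure_tolerance")
  structure(list(systolic_pressure = systolic_pressure,
                 diastolic_pressure = diastolic_pressure,
                 target_flow_fractions = f,
                 pressure_tolerance = pressure_tolerance),
            class = "clinical_targets")
}

#' Mean arterial pressure from cuff pressures
#'
#' The standard clinical estimate \eqn{MAP = DBP + (SBP - DBP)/3}: at resting
#' heart rates the heart spends roughly twice as long in diastole as systole.
#'
#' @param systolic systolic pressure (mmHg).
#' @param diastolic diastolic pressure (mmHg).
#' @return MAP (mmHg).
#' @export
#' @examples
#' mean_arterial_pressure(105, 59)  # 74.33 mmHg
mean_arterial_pressure <- function(systolic, diastolic) {
  check_positive(systolic, "systolic")
  check_positive(diastolic, "diastolic")
  if (systolic < diastolic) {
    abort_shuntr("invalid_argument", "systolic must be >= diastolic")
  }
  diastolic + (systolic - diastolic) / 3
}

#' Pressure at a single node fed by parallel outlet resistances
#'
#' Ohm-analog identity for the systemic node: a prescribed flow through
#' parallel resistances to the reference pressure gives
#' \eqn{P = P_{ref} + Q / \sum_i 1/R_i}.
#'
#' @param resistances numeric vector of outlet resistances
#'   (Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}).
#' @param flow total node throughflow (m\eqn{^3}/s).
#' @param reference_pressure downstream reference pressure (Pa).
#' @return Node pressure (Pa).
#' @export
parallel_node_pressure <- function(resistances, flow, reference_pressure = 0) {
  if (any(resistances <= 0)) {
    abort_shuntr("invalid_argument", "resistances must be positive")
  }
  check_positive(flow, "flow")
  reference_pressure + flow / sum(1 / resistances)
}

#' Calibrate systemic outlet resistances
#'
#' Single-node parallel identity: if outlet \eqn{i} is to carry the fraction
#' \eqn{f_i} of the systemic flow \eqn{Q_S} while the aortic node sits at the
#' clinical mean arterial pressure, then
#' \deqn{R_i = \frac{MAP - P_{ref}}{f_i\, Q_S}.}
#' The resulting set reproduces the MAP and the fractions exactly at the
#' calibration operating point.
#'
#' @param targets a [clinical_targets()].
#' @param systemic_flow systemic flow \eqn{Q_S} at the calibration point
#'   (m\eqn{^3}/s).
#' @param reference_pressure venous reference pressure (Pa); default 0.
#' @return Named numeric vector of resistances
#'   (Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}) for the systemic outlets.
#' @export
calibrate_outlet_resistances <- function(targets, systemic_flow,
                                         reference_pressure = 0) {
  if (!inherits(targets, "clinical_targets")) {
    abort_shuntr("invalid_argument", "`targets` must be a clinical_targets object")
  }
  check_positive(systemic_flow, "systemic_flow")
  map_pa <- mmHg_to_Pa(
    mean_arterial_pressure(targets$systolic_pressure, targets$diastolic_pressure))
  f <- targets$target_flow_fractions
  if (any(f == 0)) {
    abort_shuntr("infinite_resistance", "a zero flow fraction implies infinite resistance")
  }
  (map_pa - reference_pressure) / (f * systemic_flow)
}

#' Relative mismatch between model and clinical mean arterial pressure
#'
#' \eqn{|P_{ao}^{model} - MAP| / MAP}, using the aortic node pressure of a
#' converged solution. Comparing the result with the targets'
#' `pressure_tolerance` is the caller's acceptance check.
#'
#' @param solution a `flow_solution` (or any list with `aortic_pressure` in Pa).
#' @param targets a [clinical_targets()].
#' @return Relative error (fraction).
#' @export
pressure_match_error <- function(solution, targets) {
  if (is.null(solution$aortic_pressure)) {
    abort_shuntr("incomplete_solution", "solution lacks an aortic pressure")
  }
  map <- mean_arterial_pressure(targets$systolic_pressure,
                                targets$diastolic_pressure)
  abs(Pa_to_mmHg(solution$aortic_pressure) - map) / map
}

#' Flow fractions implied by a set of resistances
#'
#' At a single node, parallel resistances split flow as \eqn{f_i \propto 1/R_i}.
#' Used to derive default "physiological" fractions from published resistance
#' values when the distribution itself is not reported.
#'
#' @param resistances named numeric vector (any consistent unit).
#' @return Named fractions summing to 1.
#' @export
implied_flow_fractions <- function(resistances) {
  if (any(resistances <= 0)) {
    abort_shuntr("invalid_argument", "resistances must be positive")
  }
  g <- 1 / resistances
  g / sum(g)
}
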