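# Evaluation metrics: stenosis ratio, flow splits, power loss, relative
# power loss. Power loss is a total-pressure energy budget over the domain
# ports; the element-wise dissipation sum is kept as an independent check.

#' Stenosis ratio from flows
#'
#' \eqn{\alpha = Q_{MPA} / CO}: the fraction of cardiac output passing through
#' the native main pulmonary artery. \eqn{\alpha = 0} is atresia; \eqn{\alpha
#' = 1} would mean the entire output enters the lungs antegradely.
#'
#' @param mpa_flow main pulmonary artery flow (m\eqn{^3}/s).
#' @param cardiac_output cardiac output (m\eqn{^3}/s).
#' @return Dimensionless ratio in \eqn{[0, 1]}.
#' @export
stenosis_ratio <- function(mpa_flow, cardiac_output) {
  check_positive(cardiac_output, "cardiac_output")
  check_nonnegative(mpa_flow, "mpa_flow")
  if (mpa_flow > cardiac_output) {
    abort_shuntr("invalid_state", "MPA flow exceeds cardiac output")
  }
  mpa_flow / cardiac_output
}

check_solution <- function(solution) {
  if (!is.list(solution) || is.null(solution$port_states)) {
    abort_shuntr("incomplete_solution", "`solution` must carry a port_states table")
  }
  ps <- solution$port_states
  needed <- c("port", "role", "p", "v", "Q")
  if (!all(needed %in% names(ps))) {
    abort_shuntr("incomplete_solution",
                 sprintf("port_states must have columns: %s", paste(needed, collapse = ", ")))
  }
  invisible(ps)
}

#' Pulmonary/systemic and left/right flow splits
#'
#' From a converged solution: \eqn{Q_P = Q_{LPA} + Q_{RPA}},
#' \eqn{Q_S = Q_{IA} + Q_{LCA} + Q_{LSA} + Q_{DAO}}, and the two ratios
#' \eqn{Q_P/Q_S} and \eqn{Q_{LPA}/Q_{RPA}}.
#'
#' @param solution a `flow_solution` from [solve_steady()].
#' @return List with `qp_qs`, `q_lpa_rpa`, `q_p`, `q_s` (m\eqn{^3}/s).
#' @export
flow_splits <- function(solution) {
  q <- solution$element_flows
  missing <- setdiff(OUTLET_NAMES, names(q))
  if (length(missing)) {
    abort_shuntr("incomplete_solution",
                 sprintf("solution lacks outlet flows: %s", paste(missing, collapse = ", ")))
  }
  if (q[["RPA"]] == 0) {
    abort_shuntr("undefined_ratio", "RPA flow is zero; LPA/RPA split undefined")
  }
  q_p <- q[["LPA"]] + q[["RPA"]]
  q_s <- sum(q[SYSTEMIC_OUTLETS])
  if (q_s <= 0) {
    abort_shuntr("undefined_ratio", "systemic flow is non-positive; Qp/Qs undefined")
  }
  list(qp_qs = q_p / q_s, q_lpa_rpa = q[["LPA"]] / q[["RPA"]],
       q_p = q_p, q_s = q_s)
}

port_energy_flux <- function(ps, role, rho) {
  sel <- ps[ps$role == role, , drop = FALSE]
  sum((sel$p + 0.5 * rho * sel$v^2) * sel$Q)
}

#' Hemodynamic power loss
#'
#' Total-pressure energy budget over the domain ports:
#' \deqn{PL = \sum_{in} \left(p + \tfrac12 \rho v^2\right) Q
#'   - \sum_{out} \left(p + \tfrac12 \rho v^2\right) Q,}
#' with the port mean velocity \eqn{v = Q/A}. Reported in mW.
#'
#' @param solution a `flow_solution` (or any list with a complete `port_states`
#'   table and a `blood` model).
#' @param blood optional [blood_properties()] override.
#' @return Power loss (mW).
#' @export
power_loss <- function(solution, blood = NULL) {
  ps <- check_solution(solution)
  if (is.null(blood)) blood <- solution$blood
  if (is.null(blood)) {
    abort_shuntr("incomplete_solution", "no blood model available for power loss")
  }
  if (any(is.na(ps$p)) || any(is.na(ps$v)) || any(is.na(ps$Q))) {
    abort_shuntr("incomplete_solution", "port_states contains missing values")
  }
  pl <- port_energy_flux(ps, "in", blood$density) -
    port_energy_flux(ps, "out", blood$density)
  pl * 1e3
}

#' Relative power loss
#'
#' Power loss as a percentage of the total inlet energy flux:
#' \deqn{RPL = \frac{PL}{\sum_{in} (p + \tfrac12 \rho v^2)\, Q} \times 100\%.}
#' The denominator includes the flow \eqn{Q} so that the ratio is a ratio of
#' powers (dimensionless).
#'
#' @inheritParams power_loss
#' @return Relative power loss (percent).
#' @export
relative_power_loss <- function(solution, blood = NULL) {
  ps <- check_solution(solution)
  if (is.null(blood)) blood <- solution$blood
  influx <- port_energy_flux(ps, "in", blood$density)
  if (influx <= 0) {
    abort_shuntr("undefined_rpl", "inlet energy flux is non-positive; RPL undefined")
  }
  100 * (power_loss(solution, blood) / 1e3) / influx
}

#' Sum of per-element dissipations
#'
#' Independent energy bookkeeping: each element's total-pressure drop times its
#' flow, summed over the six outlet resistors and the shunt. For a mass-
#' conserving solution this equals the port-based [power_loss()] exactly;
#' the pair forms a consistency oracle for the solver's port states.
#'
#' @param solution a `flow_solution`.
#' @return Total element dissipation (mW).
#' @export
element_dissipation <- function(solution) {
  el <- solution$elements
  if (is.null(el) || !all(c("dp_total", "Q") %in% names(el))) {
    abort_shuntr("incomplete_solution", "solution lacks an element table")
  }
  sum(el$dp_total * el$Q) * 1e3
}
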