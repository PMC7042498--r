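# Oxygen mass balance of the parallel shunted circulation.
#
# Steady state: the lungs add S'VO2 to pulmonary flow, the body removes C'VO2
# from systemic flow, and uptake equals consumption:
#   Q_S (C_art - C_ven) = C'VO2      (systemic extraction)
#   Q_P (C_pv - C_art)  = S'VO2      (pulmonary uptake; mixing at the ventricle
#                                     means arterial content feeds the lungs)
# Flows in mL/min, contents in mL O2 per mL blood.

#' Oxygen transport parameters
#'
#' @param c_pv pulmonary venous O2 content (mL O2 / mL blood). Default 0.2112,
#'   i.e. 96 percent saturation at an implied capacity of 0.22 mL/mL.
#' @param cvo2 whole-body oxygen consumption (mL O2 / min); default 18.
#'   Lung oxygen uptake is constrained equal to consumption at steady state.
#' @return An `oxygen_parameters` object.
#' @export
oxygen_parameters <- function(c_pv = 0.2112, cvo2 = 18) {
  check_positive(c_pv, "c_pv")
  if (c_pv >= 0.3) {
    abort_shuntr("invalid_argument", "`c_pv` must be below 0.3 mL O2/mL blood")
  }
  check_positive(cvo2, "cvo2")
  structure(list(c_pv = c_pv, cvo2 = cvo2, svo2 = cvo2),
            class = "oxygen_parameters")
}

#' Systemic arterial oxygen content
#'
#' From the pulmonary uptake balance \eqn{Q_P (C_{pv} - C_{art}) = \dot{V}O_2}:
#' \deqn{C_{art} = C_{pv} - \frac{C\dot{V}O_2}{Q_P}.}
#'
#' @param pulmonary_flow total pulmonary flow \eqn{Q_P} (mL/min).
#' @param params an [oxygen_parameters()].
#' @return Arterial O2 content (mL O2 / mL blood).
#' @export
#' @examples
#' arterial_content(1066.3, oxygen_parameters())  # ~0.1943
arterial_content <- function(pulmonary_flow, params = oxygen_parameters()) {
  check_positive(pulmonary_flow, "pulmonary_flow")
  c_art <- params$c_pv - params$cvo2 / pulmonary_flow
  # the feasibility boundary Q_P = CVO2/C_pv is compared on flows so that the
  # boundary itself errors regardless of rounding in the content subtraction
  if (pulmonary_flow <= params$cvo2 / params$c_pv || c_art <= 0) {
    abort_shuntr("infeasible_oxygen",
                 sprintf("pulmonary flow %.4g mL/min cannot sustain total oxygen uptake (C_art <= 0)",
                         pulmonary_flow))
  }
  c_art
}

#' Systemic venous oxygen content
#'
#' From the systemic extraction balance \eqn{Q_S (C_{art} - C_{ven}) = C\dot{V}O_2}:
#' \deqn{C_{ven} = C_{art} - \frac{C\dot{V}O_2}{Q_S}.}
#'
#' @param systemic_flow systemic flow \eqn{Q_S} (mL/min).
#' @param arterial_content arterial O2 content (mL O2 / mL blood).
#' @param params an [oxygen_parameters()].
#' @return Venous O2 content (mL O2 / mL blood).
#' @export
#' @examples
#' venous_content(1055.7, 0.1943, oxygen_parameters())  # ~0.1773
venous_content <- function(systemic_flow, arterial_content,
                           params = oxygen_parameters()) {
  check_positive(systemic_flow, "systemic_flow")
  check_positive(arterial_content, "arterial_content")
  c_ven <- arterial_content - params$cvo2 / systemic_flow
  if (c_ven < 0) {
    abort_shuntr("infeasible_oxygen",
                 sprintf("systemic flow %.4g mL/min gives negative venous O2 content",
                         systemic_flow))
  }
  c_ven
}

#' Systemic oxygen delivery
#'
#' Eliminating contents from the two balances with \eqn{CO = Q_S + Q_P} and
#' \eqn{r = Q_P/Q_S} gives
#' \deqn{DO_2 = \frac{CO \cdot C_{pv}}{1 + r} - \frac{C\dot{V}O_2}{r},}
#' which equals \eqn{Q_S C_{art}}. Delivery is maximised near balanced
#' circulation (\eqn{r \approx 1}) and decays as the shunt steals systemic
#' flow into the lungs.
#'
#' @param qp_qs pulmonary-to-systemic flow ratio \eqn{r > 0}.
#' @param cardiac_output total cardiac output (mL/min).
#' @param params an [oxygen_parameters()].
#' @return Oxygen delivery DO2 (mL O2 / min).
#' @export
#' @examples
#' oxygen_delivery(1.01, 2122)  # ~205.15 mL/min
oxygen_delivery <- function(qp_qs, cardiac_output, params = oxygen_parameters()) {
  check_positive(qp_qs, "qp_qs")
  check_positive(cardiac_output, "cardiac_output")
  do2 <- cardiac_output * params$c_pv / (1 + qp_qs) - params$cvo2 / qp_qs
  if (do2 <= 0) {
    abort_shuntr("infeasible_oxygen",
                 sprintf("DO2 <= 0 at Qp/Qs = %.3g, CO = %.4g mL/min", qp_qs, cardiac_output))
  }
  do2
}

#' Full oxygen report for one operating point
#'
#' Computes arterial and venous contents and delivery from the systemic and
#' pulmonary flows, and asserts internal consistency
#' (\eqn{DO_2 = Q_S C_{art}}; uptake equals extraction).
#'
#' @param pulmonary_flow \eqn{Q_P} (mL/min).
#' @param systemic_flow \eqn{Q_S} (mL/min).
#' @param params an [oxygen_parameters()].
#' @return An `oxygen_report` list: `c_art`, `c_ven`, `do2` (mL O2/min),
#'   `qp_qs`, `q_p`, `q_s` (mL/min).
#' @export
oxygen_report <- function(pulmonary_flow, systemic_flow,
                          params = oxygen_parameters()) {
  c_art <- arterial_content(pulmonary_flow, params)
  c_ven <- venous_content(systemic_flow, c_art, params)
  r <- pulmonary_flow / systemic_flow
  co <- pulmonary_flow + systemic_flow
  do2 <- oxygen_delivery(r, co, params)
  stopifnot(abs(do2 - systemic_flow * c_art) <= 1e-9 * max(1, abs(do2)))
  structure(list(c_art = c_art, c_ven = c_ven, do2 = do2,
                 qp_qs = r, q_p = pulmonary_flow, q_s = systemic_flow),
            class = "oxygen_report")
}
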