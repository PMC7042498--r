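# Two-node steady flow network: aortic node and pulmonary node, bridged by the
# nonlinear shunt element. Inflows are prescribed ((1-alpha)*CO into the aorta,
# alpha*CO into the MPA); each outlet is a linear resistance to the venous
# reference pressure.

#' Assemble the flow network for one simulation case
#'
#' Builds the two-node topology: the aortic node receives the ascending-aorta
#' inflow \eqn{Q_{AAO} = (1-\alpha)\,CO} and feeds the four systemic outlets
#' (IA, LCA, LSA, DAO); the pulmonary node receives the native main pulmonary
#' artery inflow \eqn{Q_{MPA} = \alpha\,CO} and feeds the LPA and RPA outlets;
#' the shunt element bridges the two nodes. For \eqn{\alpha = 0} (atresia) the
#' MPA inlet is removed entirely and all pulmonary flow arrives via the shunt.
#' The LPA series resistance is multiplied by the patient's
#' `lpa_rpa_asymmetry` factor.
#'
#' @param patient a [patient_network()].
#' @param case a [case_definition()].
#' @return A `case_network` list with inlet flows, outlet resistances (SI),
#'   the per-case shunt spec and the blood model; input to [solve_steady()].
#' @export
build_case_network <- function(patient, case) {
  if (!inherits(patient, "patient_network")) {
    abort_shuntr("invalid_argument", "`patient` must be a patient_network")
  }
  if (!inherits(case, "case_definition")) {
    abort_shuntr("invalid_case", "`case` must be a case_definition")
  }
  alpha <- case$alpha
  co <- case$cardiac_output

  shunt <- patient$shunt
  shunt$diameter <- case$shunt_diameter

  r <- vapply(patient$outlets, `[[`, numeric(1), "resistance")
  r["LPA"] <- r["LPA"] * patient$lpa_rpa_asymmetry
  areas <- vapply(patient$outlets, `[[`, numeric(1), "area")

  inlets <- data.frame(
    name = c("AAO", "MPA"),
    node = c("aortic", "pulmonary"),
    flow = c((1 - alpha) * co, alpha * co),
    area = c(patient$aortic_root_area, patient$mpa_area),
    stringsAsFactors = FALSE
  )
  if (alpha == 0) inlets <- inlets[inlets$name == "AAO", , drop = FALSE]

  outlets <- data.frame(
    name = OUTLET_NAMES,
    node = c(rep("aortic", 4L), rep("pulmonary", 2L)),
    resistance = unname(r[OUTLET_NAMES]),
    area = unname(areas[OUTLET_NAMES]),
    stringsAsFactors = FALSE
  )

  structure(list(
    inlets = inlets, outlets = outlets, shunt = shunt,
    blood = patient$blood, reference_pressure = patient$reference_pressure,
    case = case
  ), class = "case_network")
}

# linear 2x2 nodal solve with a fixed shunt conductance g_sh; returns node
# pressures relative to absolute zero (reference pressure handled explicitly)
linear_nodal_solution <- function(q_ao, q_pa, g_sys, g_pul, g_sh, p_ref) {
  A <- matrix(c(g_sys + g_sh, -g_sh,
                -g_sh, g_pul + g_sh), 2, 2, byrow = TRUE)
  b <- c(q_ao + g_sys * p_ref, q_pa + g_pul * p_ref)
  as.numeric(solve(A, b))
}

#' Solve steady-state pressures and flows for an assembled network
#'
#' Damped Newton iteration on the two node pressures. The residual at each
#' node is the flow imbalance (m\eqn{^3}/s); the shunt flow is obtained from
#' the node pressure difference through the closed-form inverse of the shunt
#' law, so the nonlinear constitutive relation is satisfied exactly at every
#' iterate. The initial guess is the linearised network (minor loss dropped).
#'
#' Convergence demands a maximum absolute nodal flow residual below `tol`
#' (default 1e-10 m\eqn{^3}/s, stricter than the 1e-8 kg/s mass-conservation
#' contract reported in the solution). A converged solution with reversed
#' (negative aorta-to-PA) shunt flow is flagged via `shunt_reversed` and a
#' warning, never silently accepted.
#'
#' @param network a `case_network` from [build_case_network()].
#' @param blood optional [blood_properties()] override; defaults to the blood
#'   model carried by the network.
#' @param tol absolute nodal flow-residual tolerance (m\eqn{^3}/s).
#' @param max_iter maximum Newton iterations.
#' @return A `flow_solution` with node pressures (Pa), per-element flows
#'   (m\eqn{^3}/s), port states (static pressure, mean velocity, flow per
#'   inlet/outlet port), an element table with total-pressure dissipation,
#'   the mass residual (kg/s) and iteration count.
#' @export
solve_steady <- function(network, blood = NULL, tol = 1e-10, max_iter = 100L) {
  if (!inherits(network, "case_network")) {
    abort_shuntr("invalid_argument", "`network` must come from build_case_network()")
  }
  if (is.null(blood)) blood <- network$blood
  p_ref <- network$reference_pressure

  sys <- network$outlets[network$outlets$node == "aortic", ]
  pul <- network$outlets[network$outlets$node == "pulmonary", ]
  g_sys <- sum(1 / sys$resistance)
  g_pul <- sum(1 / pul$resistance)
  q_ao <- sum(network$inlets$flow[network$inlets$node == "aortic"])
  q_pa <- sum(network$inlets$flow[network$inlets$node == "pulmonary"])

  a <- shunt_linear_coefficient(network$shunt, blood)
  b <- shunt_quadratic_coefficient(network$shunt, blood)

  residual_fun <- function(p) {
    dp <- p[1] - p[2]
    q_sh <- shunt_flow_from_dp(dp, a, b)
    c(q_ao - g_sys * (p[1] - p_ref) - q_sh,
      q_pa + q_sh - g_pul * (p[2] - p_ref))
  }

  p <- linear_nodal_solution(q_ao, q_pa, g_sys, g_pul, 1 / a, p_ref)
  f <- residual_fun(p)
  iter <- 0L
  # iterate to the numerical floor (stop when the residual no longer
  # improves); `tol` is the convergence contract, but polishing past it keeps
  # the nodal balance -- and hence the port/element energy identity -- at
  # machine precision
  while (max(abs(f)) > 0 && iter < max_iter) {
    q_sh <- shunt_flow_from_dp(p[1] - p[2], a, b)
    g_sh <- 1 / (a + 2 * b * abs(q_sh))  # d q_sh / d dp
    J <- matrix(c(-g_sys - g_sh, g_sh,
                  g_sh, -g_pul - g_sh), 2, 2, byrow = TRUE)
    step <- solve(J, -f)
    lambda <- 1
    repeat {
      p_new <- p + lambda * step
      f_new <- residual_fun(p_new)
      if (sum(f_new^2) < sum(f^2) || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    if (sum(f_new^2) >= sum(f^2)) break  # stalled at the rounding floor
    p <- p_new
    f <- f_new
    iter <- iter + 1L
  }
  converged <- max(abs(f)) <= tol
  if (!converged) {
    abort_shuntr("solver_error",
                 sprintf("steady solver did not converge in %d iterations (last residual %.3e m^3/s)",
                         max_iter, max(abs(f))),
                 residual = max(abs(f)))
  }

  q_sh <- shunt_flow_from_dp(p[1] - p[2], a, b)
  shunt_reversed <- q_sh < 0
  if (shunt_reversed) {
    warning(warningCondition(
      sprintf("shunt flow is reversed (PA to aorta): Q = %.3e m^3/s", q_sh),
      class = c("shuntr_reversed_shunt", "shuntr_warning", "warning", "condition")
    ))
  }

  node_p <- c(aortic = p[1], pulmonary = p[2])
  out_q <- (node_p[network$outlets$node] - p_ref) / network$outlets$resistance
  names(out_q) <- network$outlets$name

  inl <- network$inlets
  rho <- blood$density
  # kinetic head at each node: the inlet port velocity (0 for an absent inlet)
  node_kin <- c(aortic = 0, pulmonary = 0)
  for (i in seq_len(nrow(inl))) {
    node_kin[inl$node[i]] <- 0.5 * rho * (inl$flow[i] / inl$area[i])^2
  }

  ports <- rbind(
    data.frame(port = inl$name, role = "in", node = inl$node,
               p = unname(node_p[inl$node]),
               v = inl$flow / inl$area, Q = inl$flow, area = inl$area,
               stringsAsFactors = FALSE),
    data.frame(port = network$outlets$name, role = "out",
               node = network$outlets$node,
               p = p_ref,
               v = unname(out_q) / network$outlets$area, Q = unname(out_q),
               area = network$outlets$area, stringsAsFactors = FALSE)
  )
  rownames(ports) <- NULL

  # element total-pressure states: upstream at the node (static + node kinetic
  # head), downstream at the port (reference static + port kinetic head)
  elements <- rbind(
    data.frame(element = network$outlets$name, from = network$outlets$node,
               to = "reference", Q = unname(out_q),
               dp_static = unname(node_p[network$outlets$node]) - p_ref,
               dp_total = unname(node_p[network$outlets$node] +
                                   node_kin[network$outlets$node]) -
                 (p_ref + 0.5 * rho * (unname(out_q) / network$outlets$area)^2),
               stringsAsFactors = FALSE),
    data.frame(element = "shunt", from = "aortic", to = "pulmonary",
               Q = q_sh,
               dp_static = unname(node_p["aortic"] - node_p["pulmonary"]),
               dp_total = unname(node_p["aortic"] + node_kin["aortic"] -
                                   node_p["pulmonary"] - node_kin["pulmonary"]),
               stringsAsFactors = FALSE)
  )
  elements$dissipation <- elements$dp_total * elements$Q
  rownames(elements) <- NULL

  mass_residual <- rho * abs(sum(inl$flow) - sum(out_q))

  element_flows <- c(out_q, shunt = unname(q_sh))

  structure(list(
    aortic_pressure = unname(node_p["aortic"]),
    pulmonary_pressure = unname(node_p["pulmonary"]),
    reference_pressure = p_ref,
    element_flows = element_flows,
    port_states = ports,
    elements = elements,
    blood = blood,
    case = network$case,
    shunt = network$shunt,
    shunt_reversed = shunt_reversed,
    converged = TRUE,
    residual = unname(mass_residual),
    flow_residual = max(abs(f)),
    iterations = iter
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>\n")
  cat(sprintf("  P_ao = %.1f Pa (%.1f mmHg), P_pa = %.1f Pa (%.1f mmHg)\n",
              x$aortic_pressure, Pa_to_mmHg(x$aortic_pressure),
              x$pulmonary_pressure, Pa_to_mmHg(x$pulmonary_pressure)))
  cat(sprintf("  shunt flow = %.4g m^3/s (%.3f L/min)%s\n",
              x$element_flows[["shunt"]], m3s_to_lmin(x$element_flows[["shunt"]]),
              if (x$shunt_reversed) " [REVERSED]" else ""))
  cat(sprintf("  mass residual = %.2e kg/s, %d Newton iterations\n",
              x$residual, x$iterations))
  invisible(x)
}

#' Solve one case directly from patient and case definitions
#'
#' Convenience wrapper: [build_case_network()] followed by [solve_steady()].
#'
#' @inheritParams build_case_network
#' @param ... passed to [solve_steady()].
#' @return A `flow_solution`.
#' @export
solve_case <- function(patient, case, ...) {
  solve_steady(build_case_network(patient, case), ...)
}
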