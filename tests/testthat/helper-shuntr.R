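# Shared fixtures and independent oracles.

ref_blood <- function() blood_properties(1060, 0.005)

# independent linear 2x2 nodal oracle (K = 0 shunt): written directly from the
# Kirchhoff balance, no shared code with solve_steady()
linear_oracle <- function(patient, case) {
  r <- vapply(patient$outlets, `[[`, numeric(1), "resistance")
  r["LPA"] <- r["LPA"] * patient$lpa_rpa_asymmetry
  g_sys <- sum(1 / r[c("IA", "LCA", "LSA", "DAO")])
  g_pul <- sum(1 / r[c("LPA", "RPA")])
  mu <- patient$blood$viscosity
  d <- case$shunt_diameter
  g_sh <- pi * d^4 / (128 * mu * patient$shunt$length)
  q_ao <- (1 - case$alpha) * case$cardiac_output
  q_pa <- case$alpha * case$cardiac_output
  p_ref <- patient$reference_pressure
  A <- matrix(c(g_sys + g_sh, -g_sh, -g_sh, g_pul + g_sh), 2, 2, byrow = TRUE)
  b <- c(q_ao + g_sys * p_ref, q_pa + g_pul * p_ref)
  p <- solve(A, b)
  list(p_ao = p[1], p_pa = p[2], q_sh = g_sh * (p[1] - p[2]))
}

# reference patient with the shunt minor loss switched off (linear network)
linear_patient <- function() {
  p <- reference_patient()
  p$shunt$minor_loss_coefficient <- 0
  p
}

# patient with a single effective systemic outlet: make the other three
# resistances enormous so essentially all systemic flow passes through IA
grid_cases <- function() {
  out <- list()
  k <- 0L
  for (d in GRID_DIAMETERS_MM_t()) {
    for (a in GRID_ALPHAS_t()) {
      k <- k + 1L
      out[[k]] <- case_definition(d * 1e-3, a,
                                  lmin_to_m3s(cardiac_output_for_diameter(d)))
    }
  }
  out
}

GRID_DIAMETERS_MM_t <- function() c(3, 3.5, 4, 4.5, 5)
GRID_ALPHAS_t <- function() c(0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30)

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            rel_tol)
}
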