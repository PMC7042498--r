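test_that("build_case_network splits the cardiac output per the stenosis ratio", {
  p <- reference_patient()
  co <- lmin_to_m3s(2.798)
  net <- build_case_network(p, case_definition(0.005, 0.30, co))
  # alpha * CO through the native MPA: 0.3 * 2.798 = 0.8394 L/min
  q_mpa <- net$inlets$flow[net$inlets$name == "MPA"]
  expect_equal(m3s_to_lmin(q_mpa), 0.8394, tolerance = 1e-12)
  expect_equal(sum(net$inlets$flow), co)

  # atresia: MPA inlet removed entirely
  net0 <- build_case_network(p, case_definition(0.003, 0, lmin_to_m3s(2.122)))
  expect_identical(net0$inlets$name, "AAO")

  # topology counts
  net4 <- build_case_network(p, case_definition(0.004, 0.15, lmin_to_m3s(2.458)))
  expect_identical(nrow(net4$inlets), 2L)
  expect_identical(nrow(net4$outlets), 6L)
  expect_identical(sort(net4$outlets$node[net4$outlets$node == "aortic"]),
                   rep("aortic", 4L))

  expect_error(case_definition(0.004, 1.0, co), class = "shuntr_invalid_case")
  expect_error(case_definition(0.004, -0.1, co), class = "shuntr_invalid_case")
})

test_that("single-outlet network reproduces the closed-form Ohm analog", {
  # all systemic resistance funneled into IA by making the others huge;
  # pulmonary side symmetric
  p <- reference_patient()
  big <- 1e20
  for (nm in c("LCA", "LSA", "DAO")) p$outlets[[nm]]$resistance <- big
  p$shunt$minor_loss_coefficient <- 0
  p$reference_pressure <- 500  # nonzero reference to exercise the offset
  case <- case_definition(0.004, 0, lmin_to_m3s(2.458))
  sol <- solve_case(p, case)
  # node pressure = R * Q + reference for the dominating resistor
  q_ia <- sol$element_flows[["IA"]]
  r_ia <- p$outlets$IA$resistance
  expect_rel_equal(sol$aortic_pressure, r_ia * q_ia + 500, 1e-12)
})

test_that("solver agrees with the independent linear nodal oracle (K = 0)", {
  p <- linear_patient()
  for (case in grid_cases()) {
    sol <- solve_case(p, case)
    ora <- linear_oracle(p, case)
    expect_rel_equal(sol$aortic_pressure, ora$p_ao, 1e-10)
    expect_rel_equal(sol$pulmonary_pressure, ora$p_pa, 1e-10)
    expect_rel_equal(sol$element_flows[["shunt"]], ora$q_sh, 1e-10)
  }
})

test_that("mass conservation holds across every grid case", {
  p <- reference_patient()
  for (case in grid_cases()) {
    sol <- solve_case(p, case)
    expect_true(sol$converged)
    expect_lte(sol$residual, 1e-8)  # kg/s
    expect_true(all(sol$element_flows[c("IA","LCA","LSA","DAO","LPA","RPA")] >= 0))
  }
})

test_that("symmetric pulmonary resistances give an exactly symmetric split", {
  p <- reference_patient()
  stopifnot(p$lpa_rpa_asymmetry == 1)
  sol <- solve_case(p, case_definition(0.004, 0.15, lmin_to_m3s(2.458)))
  expect_identical(sol$element_flows[["LPA"]], sol$element_flows[["RPA"]])
})

test_that("total pulmonary flow is monotone in diameter and in alpha", {
  p <- reference_patient()
  qp <- matrix(NA_real_, nrow = 5, ncol = 7)
  ds <- GRID_DIAMETERS_MM_t()
  as <- GRID_ALPHAS_t()
  for (i in seq_along(ds)) for (j in seq_along(as)) {
    case <- case_definition(ds[i] * 1e-3, as[j],
                            lmin_to_m3s(cardiac_output_for_diameter(ds[i])))
    sol <- solve_case(p, case)
    qp[i, j] <- sol$element_flows[["LPA"]] + sol$element_flows[["RPA"]]
  }
  expect_true(all(apply(qp, 2, function(col) all(diff(col) >= 0))))  # in d
  expect_true(all(apply(qp, 1, function(row) all(diff(row) >= 0))))  # in alpha
})

test_that("reversed shunt flow is flagged, not silently accepted", {
  p <- reference_patient()
  # inflate pulmonary downstream resistance so the prescribed MPA inflow
  # drives the pulmonary node above aortic pressure
  p$outlets$LPA$resistance <- MPa_s_m3_to_SI(5e5)
  p$outlets$RPA$resistance <- MPa_s_m3_to_SI(5e5)
  case <- case_definition(0.003, 0.30, lmin_to_m3s(2.122))
  expect_warning(sol <- solve_case(p, case), class = "shuntr_reversed_shunt")
  expect_true(sol$shunt_reversed)
  expect_lt(sol$element_flows[["shunt"]], 0)
})

test_that("solution export writes a complete JSON record", {
  sol <- solve_case(reference_patient(),
                    case_definition(0.004, 0.15, lmin_to_m3s(2.458)))
  path <- withr::local_tempfile(fileext = ".json")
  write_solution_json(sol, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$node_pressures_Pa$aortic, sol$aortic_pressure)
  expect_equal(js$element_flows_m3_s$shunt, sol$element_flows[["shunt"]])
  expect_true(js$converged)
  expect_equal(js$iterations, sol$iterations)
})
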