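printed_sys_R <- function() {
  MPa_s_m3_to_SI(c(IA = 2383, LCA = 4792, LSA = 4260, DAO = 1152))
}

test_that("mean arterial pressure is DBP + PP/3", {
  expect_equal(mean_arterial_pressure(105, 59), 59 + (105 - 59) / 3)
  expect_equal(mean_arterial_pressure(105, 59), 74.33, tolerance = 1e-4)
  expect_identical(mean_arterial_pressure(80, 80), 80)  # zero pulse pressure
  m <- mean_arterial_pressure(120, 70)
  expect_true(m > 70 && m < 120)
  expect_error(mean_arterial_pressure(59, 105), class = "shuntr_invalid_argument")
})

test_that("single-outlet calibration is the Ohm analog", {
  t1 <- clinical_targets(80, 80, c(IA = 1 - 3e-13, LCA = 1e-13, LSA = 1e-13,
                                   DAO = 1e-13))
  q_s <- 2e-5
  r <- calibrate_outlet_resistances(t1, q_s)
  expect_rel_equal(r[["IA"]], mmHg_to_Pa(80) / q_s, 1e-9)
})

test_that("fractions implied by the published resistances recover them exactly", {
  r_sys <- printed_sys_R()
  f <- implied_flow_fractions(r_sys)
  expect_equal(sum(f), 1, tolerance = 1e-15)
  # operating point where the parallel set produces the clinical MAP
  map_pa <- mmHg_to_Pa(mean_arterial_pressure(105, 59))
  q_s <- map_pa * sum(1 / r_sys)
  targets <- clinical_targets(105, 59, f)
  # MAP used inside calibration is DBP+PP/3 on (105, 59) = the same map_pa
  r_cal <- calibrate_outlet_resistances(targets, q_s)
  for (nm in names(r_sys)) expect_rel_equal(r_cal[[nm]], r_sys[[nm]], 1e-10)
})

test_that("calibrate -> solve -> measure round-trips on seeded virtual patients", {
  n_ok <- 0L
  n <- 100L
  for (seed in seq_len(n)) {
    p <- generate_patient(patient_generator_config(seed = seed))
    r_true <- vapply(p$outlets[c("IA", "LCA", "LSA", "DAO")], `[[`,
                     numeric(1), "resistance")
    q_s <- lmin_to_m3s(1.05)
    # forward model at the calibration point: node pressure and flow fractions
    p_node <- parallel_node_pressure(r_true, q_s)
    f <- implied_flow_fractions(r_true)
    map_mmHg <- Pa_to_mmHg(p_node)
    targets <- clinical_targets(map_mmHg, map_mmHg, f)  # zero pulse pressure
    r_cal <- calibrate_outlet_resistances(targets, q_s)
    # measure: the calibrated network reproduces pressure and fractions
    p_back <- parallel_node_pressure(r_cal, q_s)
    f_back <- implied_flow_fractions(r_cal)
    ok <- all(abs(r_cal - r_true) / r_true <= 1e-8) &&
      abs(p_back - p_node) / p_node <= 1e-8 &&
      all(abs(f_back - f) <= 1e-8)
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok, 0.99 * n)
})

test_that("pressure match error behaves linearly and hits the worked value", {
  targets <- clinical_targets(105, 59,
                              implied_flow_fractions(printed_sys_R()))
  map <- mean_arterial_pressure(105, 59)
  # exact match -> zero error
  expect_equal(pressure_match_error(list(aortic_pressure = mmHg_to_Pa(map)),
                                    targets), 0)
  # doubling the model pressure doubles the error
  e1 <- pressure_match_error(list(aortic_pressure = mmHg_to_Pa(map * 1.1)), targets)
  e2 <- pressure_match_error(list(aortic_pressure = mmHg_to_Pa(map * 1.2)), targets)
  expect_equal(e2, 2 * e1, tolerance = 1e-10)

  # published operating point: Qs = CO/(1+1.01), CO = 2.122 L/min, printed
  # resistances in parallel -> ~2.6% mismatch, inside the 5% bound
  q_s <- lmin_to_m3s(2.122) / (1 + 1.01)
  p_model <- parallel_node_pressure(printed_sys_R(), q_s)
  err <- pressure_match_error(list(aortic_pressure = p_model), targets)
  expect_equal(err, 0.0256, tolerance = 0.01)
  expect_lt(err, targets$pressure_tolerance)
})

test_that("degenerate calibration inputs raise typed errors", {
  expect_error(clinical_targets(105, 59, c(IA = 0.5, LCA = 0.5, LSA = 0.5,
                                           DAO = 0.5)),
               class = "shuntr_invalid_argument")
  expect_error(clinical_targets(105, 59, c(IA = 0.5, BAD = 0.5)),
               class = "shuntr_invalid_argument")
  expect_error(implied_flow_fractions(c(IA = -1, LCA = 2)),
               class = "shuntr_invalid_argument")
})
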