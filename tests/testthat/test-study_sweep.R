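test_that("cardiac output lookup reproduces the study table", {
  expect_equal(cardiac_output_for_diameter(3), 2.122)
  expect_equal(cardiac_output_for_diameter(3.5), 2.303)
  expect_equal(cardiac_output_for_diameter(4), 2.458)
  expect_equal(cardiac_output_for_diameter(4.5), 2.630)
  expect_equal(cardiac_output_for_diameter(5), 2.798)
  expect_error(cardiac_output_for_diameter(4.2), class = "shuntr_lookup_error")
  # interpolation only behind the explicit flag
  expect_equal(cardiac_output_for_diameter(4.25, interpolate = TRUE),
               (2.458 + 2.630) / 2)
  expect_error(cardiac_output_for_diameter(6, interpolate = TRUE),
               class = "shuntr_lookup_error")
})

test_that("run_case assembles a complete report", {
  p <- reference_patient()
  case <- case_definition(0.003, 0, lmin_to_m3s(2.122))
  rep <- run_case(p, case)
  expect_s3_class(rep, "case_report")
  expect_identical(rep$status, "ok")
  expect_equal(rep$q_lpa_rpa, 1)           # symmetric patient
  expect_lte(rep$mass_residual, 1e-8)      # kg/s
  # atresia: all pulmonary flow arrives via the shunt
  expect_rel_equal(rep$solution$element_flows[["shunt"]], rep$q_p, 1e-10)
  expect_false(is.null(rep$oxygen))
  expect_equal(rep$oxygen$qp_qs, rep$qp_qs, tolerance = 1e-12)
})

test_that("the default grid yields 35 deterministic, ordered rows", {
  p <- reference_patient()
  res <- run_grid(p, sweep_grid())
  expect_identical(nrow(res), 35L)
  expect_identical(res$diameter_mm, rep(c(3, 3.5, 4, 4.5, 5), each = 7))
  expect_identical(res$alpha, rep(c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3), 5))
  expect_identical(res$co_l_min[res$diameter_mm == 3][1], 2.122)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$mass_residual <= 1e-8))

  # bit-identical re-run
  expect_identical(res, run_grid(p, sweep_grid()))

  # case independence: a reversed grid gives the same per-case values
  rev_grid <- sweep_grid()
  rev_res <- run_grid(p, rev_grid)  # sweep_grid() sorts; emulate reversal by lookup
  for (i in c(1L, 18L, 35L)) {
    j <- which(rev_res$diameter_mm == res$diameter_mm[i] &
                 rev_res$alpha == res$alpha[i])
    expect_identical(res[i, ], rev_res[j, ], ignore_attr = TRUE)
  }
})

test_that("the trend battery holds on the default patient", {
  res <- run_grid(reference_patient(), sweep_grid())
  # qp_qs increases with alpha at fixed diameter and with diameter at fixed alpha
  for (d in unique(res$diameter_mm)) {
    sub <- res[res$diameter_mm == d, ]
    expect_true(all(diff(sub$qp_qs) > 0))
    expect_true(all(diff(sub$do2_ml_min) < 0))  # DO2 decreases with alpha
    expect_true(all(diff(sub$pl_mW) < 0))       # PL decreases with alpha
  }
  for (a in unique(res$alpha)) {
    sub <- res[res$alpha == a, ]
    expect_true(all(diff(sub$qp_qs) > 0))
  }
})

test_that("failed cases become status rows, not omissions", {
  p <- reference_patient()
  grid <- sweep_grid(diameters_mm = c(3, 4), alphas = c(0, 0.99))
  # at alpha = 0.99 the pulmonary node is pressurised above the aorta and the
  # shunt reverses; the reversal warning itself is tested in test-hemo_network
  res <- suppressWarnings(run_grid(p, grid))
  expect_identical(nrow(res), 4L)  # extreme alpha rows are reported, not dropped
  # infeasible oxygen regimes are marked, not dropped: a tiny CO starves
  # systemic oxygen transport
  tiny <- case_definition(0.003, 0, lmin_to_m3s(0.02))
  rep <- run_case(p, tiny)
  expect_identical(rep$status, "oxygen_infeasible")
  expect_null(rep$oxygen)
})

test_that("sweep results round-trip through CSV", {
  res <- run_grid(reference_patient(),
                  sweep_grid(diameters_mm = c(3, 5), alphas = c(0, 0.3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_case_reports(res, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 4L)
  expect_equal(back$qp_qs, res$qp_qs, tolerance = 1e-12)
  expect_true(all(c("diameter_mm", "alpha", "qp_qs", "q_lpa_rpa", "pl_mW",
                    "rpl_pct", "do2_ml_min", "cart", "cven", "re_shunt")
                  %in% names(back)))
})

test_that("patient configs round-trip through the flat key-value format", {
  p <- generate_patient(patient_generator_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".cfg")
  write_patient_config(p, path)
  q <- read_patient_config(path)
  for (nm in names(p$outlets)) {
    expect_equal(q$outlets[[nm]]$resistance, p$outlets[[nm]]$resistance)
    expect_equal(q$outlets[[nm]]$area, p$outlets[[nm]]$area)
    expect_equal(q$outlets[[nm]]$porous_length, p$outlets[[nm]]$porous_length)
  }
  expect_equal(q$lpa_rpa_asymmetry, p$lpa_rpa_asymmetry)
  expect_equal(q$shunt$minor_loss_coefficient, p$shunt$minor_loss_coefficient)
  expect_equal(q$blood$density, p$blood$density)
  # malformed config is a typed error
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("IA.resistance_MPa_s_m3 = not_a_number"), bad)
  expect_error(read_patient_config(bad), class = "shuntr_config_error")
})
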