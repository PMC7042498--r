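# Flat key-value patient configs and JSON solution export.
#
# Config format: one `key = value` per line, `#` comments allowed. Outlet keys
# are <NAME>.<field> with fields resistance_MPa_s_m3, area_m2, porous_length_m;
# scalar keys: blood.density_kg_m3, blood.viscosity_Pa_s, shunt.length_m,
# shunt.minor_loss_k, lpa_rpa_asymmetry, aortic_root_area_m2, mpa_area_m2,
# reference_pressure_Pa.

#' Write a patient network to a flat key-value config file
#'
#' @param patient a [patient_network()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_patient_config <- function(patient, path) {
  if (!inherits(patient, "patient_network")) {
    abort_shuntr("invalid_argument", "`patient` must be a patient_network")
  }
  lines <- c("# shuntr patient config (flat key = value)")
  fmt <- function(key, value) sprintf("%s = %.17g", key, value)
  for (nm in OUTLET_NAMES) {
    o <- patient$outlets[[nm]]
    lines <- c(lines,
               fmt(paste0(nm, ".resistance_MPa_s_m3"), SI_to_MPa_s_m3(o$resistance)),
               fmt(paste0(nm, ".area_m2"), o$area),
               fmt(paste0(nm, ".porous_length_m"), o$porous_length))
  }
  lines <- c(lines,
             fmt("blood.density_kg_m3", patient$blood$density),
             fmt("blood.viscosity_Pa_s", patient$blood$viscosity),
             fmt("shunt.length_m", patient$shunt$length),
             fmt("shunt.minor_loss_k", patient$shunt$minor_loss_coefficient),
             fmt("lpa_rpa_asymmetry", patient$lpa_rpa_asymmetry),
             fmt("aortic_root_area_m2", patient$aortic_root_area),
             fmt("mpa_area_m2", patient$mpa_area),
             fmt("reference_pressure_Pa", patient$reference_pressure))
  writeLines(lines, path)
  invisible(path)
}

parse_kv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    abort_shuntr("config_error",
                 sprintf("malformed config line(s): %s", paste(lines[bad], collapse = "; ")))
  }
  vals <- vapply(kv, function(m) m[3], character(1))
  names(vals) <- vapply(kv, function(m) m[2], character(1))
  out <- suppressWarnings(as.numeric(vals))
  if (any(is.na(out))) {
    abort_shuntr("config_error",
                 sprintf("non-numeric config value for: %s",
                         paste(names(vals)[is.na(out)], collapse = ", ")))
  }
  names(out) <- names(vals)
  out
}

#' Read a patient network from a flat key-value config file
#'
#' @param path config file written by [write_patient_config()] (or by hand in
#'   the same format).
#' @return A [patient_network()].
#' @export
read_patient_config <- function(path) {
  kv <- parse_kv_lines(path)
  need <- function(key) {
    if (!key %in% names(kv)) {
      abort_shuntr("config_error", sprintf("missing config key: %s", key))
    }
    unname(kv[[key]])
  }
  outlets <- lapply(OUTLET_NAMES, function(nm) {
    outlet_bc(nm,
              resistance = MPa_s_m3_to_SI(need(paste0(nm, ".resistance_MPa_s_m3"))),
              area = need(paste0(nm, ".area_m2")),
              porous_length = need(paste0(nm, ".porous_length_m")))
  })
  patient_network(
    blood = blood_properties(need("blood.density_kg_m3"),
                             need("blood.viscosity_Pa_s")),
    outlets = outlets,
    shunt = shunt_spec(diameter = 0.004, length = need("shunt.length_m"),
                       minor_loss_coefficient = need("shunt.minor_loss_k")),
    lpa_rpa_asymmetry = need("lpa_rpa_asymmetry"),
    aortic_root_area = need("aortic_root_area_m2"),
    mpa_area = need("mpa_area_m2"),
    reference_pressure = need("reference_pressure_Pa")
  )
}

#' Export a flow solution as JSON
#'
#' Serialises node pressures (Pa), element flows (m\eqn{^3}/s), port states,
#' the mass residual (kg/s) and the iteration count.
#'
#' @param solution a `flow_solution`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  if (!inherits(solution, "flow_solution")) {
    abort_shuntr("invalid_argument", "`solution` must be a flow_solution")
  }
  obj <- list(
    node_pressures_Pa = list(aortic = solution$aortic_pressure,
                             pulmonary = solution$pulmonary_pressure),
    reference_pressure_Pa = solution$reference_pressure,
    element_flows_m3_s = as.list(solution$element_flows),
    port_states = solution$port_states,
    mass_residual_kg_s = solution$residual,
    iterations = solution$iterations,
    converged = solution$converged,
    shunt_reversed = solution$shunt_reversed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
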