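# Virtual-patient generation. The reference patient carries the published
# boundary-condition set; generated patients perturb it with seeded, positive
# (log-normal) resistance noise and uniform geometry draws, standing in for
# patient-to-patient anatomical variability.

REFERENCE_RESISTANCES_MPA <- c(IA = 2383, LCA = 4792, LSA = 4260,
                               DAO = 1152, LPA = 131, RPA = 131)

# pediatric-scale lumen diameters (m); the published set has no lumen sizes,
# so these are fixed package defaults
REFERENCE_DIAMETERS_M <- c(IA = 0.005, LCA = 0.003, LSA = 0.003,
                           DAO = 0.008, LPA = 0.005, RPA = 0.005)

#' The reference virtual patient
#'
#' Deterministic patient with the published boundary-condition set: outlet
#' resistances 2383, 4792, 4260, 1152, 131 and 131
#' MPa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}} for IA, LCA, LSA, DAO, LPA and RPA,
#' blood density 1060 kg/m\eqn{^3}, viscosity 0.005 Pa\eqn{\cdot}s, a
#' symmetric pulmonary split (`lpa_rpa_asymmetry = 1`), a 20 mm shunt with
#' minor-loss coefficient 1.5, and pediatric-scale lumen areas
#' (12 mm ascending aorta, 8 mm MPA, 3--8 mm branches).
#'
#' @return A [patient_network()].
#' @export
#' @examples
#' reference_patient()
reference_patient <- function() {
  outlets <- lapply(OUTLET_NAMES, function(nm) {
    outlet_bc(nm,
              resistance = MPa_s_m3_to_SI(REFERENCE_RESISTANCES_MPA[[nm]]),
              area = pi * (REFERENCE_DIAMETERS_M[[nm]] / 2)^2,
              porous_length = 0.01)
  })
  patient_network(
    blood = blood_properties(density = 1060, viscosity = 0.005),
    outlets = outlets,
    shunt = shunt_spec(diameter = 0.004, length = 0.02,
                       minor_loss_coefficient = 1.5),
    lpa_rpa_asymmetry = 1
  )
}

#' Configuration of the virtual-patient generator
#'
#' @param seed integer seed; identical seeds yield identical patients.
#' @param resistance_cv coefficient of variation of the log-normal
#'   perturbation applied to each of the six reference resistances
#'   (default 0.2; 0 disables resistance noise).
#' @param area_scale_range multiplicative bounds for lumen areas, drawn
#'   uniformly per vessel around the reference areas.
#' @param asymmetry_range bounds for the LPA/RPA asymmetry factor.
#' @param shunt_k_range bounds for the shunt minor-loss coefficient K.
#' @return A `patient_generator_config` object.
#' @export
patient_generator_config <- function(seed = 1L,
                                     resistance_cv = 0.2,
                                     area_scale_range = c(0.8, 1.2),
                                     asymmetry_range = c(0.8, 1.25),
                                     shunt_k_range = c(1.0, 2.0)) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_shuntr("config_error", "`seed` must be a single integer")
  }
  check_nonnegative(resistance_cv, "resistance_cv")
  for (nm in c("area_scale_range", "asymmetry_range", "shunt_k_range")) {
    rng <- get(nm)
    if (length(rng) != 2L || any(!is.finite(rng)) || any(rng <= 0) || rng[1] > rng[2]) {
      abort_shuntr("config_error",
                   sprintf("`%s` must be positive finite bounds with lower <= upper", nm))
    }
  }
  structure(list(seed = as.integer(seed), resistance_cv = resistance_cv,
                 area_scale_range = area_scale_range,
                 asymmetry_range = asymmetry_range,
                 shunt_k_range = shunt_k_range),
            class = "patient_generator_config")
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  force(code)
}

#' Generate a seeded virtual patient
#'
#' Resistances are drawn log-normally with median at the reference values and
#' the configured coefficient of variation (log-normal keeps them positive);
#' lumen areas are scaled by uniform per-vessel factors; the LPA/RPA asymmetry
#' and the shunt minor-loss coefficient are drawn uniformly in their ranges.
#' The caller's RNG state is left untouched.
#'
#' @param config a [patient_generator_config()].
#' @return A [patient_network()] satisfying all network invariants.
#' @export
#' @examples
#' p <- generate_patient(patient_generator_config(seed = 42))
generate_patient <- function(config = patient_generator_config()) {
  if (!inherits(config, "patient_generator_config")) {
    abort_shuntr("config_error", "`config` must be a patient_generator_config")
  }
  ref <- reference_patient()
  with_preserved_rng({
    set.seed(config$seed)
    sdlog <- sqrt(log(1 + config$resistance_cv^2))
    r_mult <- stats::rlnorm(length(OUTLET_NAMES), meanlog = 0, sdlog = sdlog)
    a_mult <- stats::runif(length(OUTLET_NAMES),
                           config$area_scale_range[1], config$area_scale_range[2])
    asym <- stats::runif(1, config$asymmetry_range[1], config$asymmetry_range[2])
    k <- stats::runif(1, config$shunt_k_range[1], config$shunt_k_range[2])

    outlets <- lapply(seq_along(OUTLET_NAMES), function(i) {
      o <- ref$outlets[[OUTLET_NAMES[i]]]
      outlet_bc(o$name, resistance = o$resistance * r_mult[i],
                area = o$area * a_mult[i], porous_length = o$porous_length)
    })
    patient_network(
      blood = ref$blood,
      outlets = outlets,
      shunt = shunt_spec(diameter = ref$shunt$diameter,
                         length = ref$shunt$length,
                         minor_loss_coefficient = k),
      lpa_rpa_asymmetry = asym,
      aortic_root_area = ref$aortic_root_area,
      mpa_area = ref$mpa_area,
      reference_pressure = ref$reference_pressure
    )
  })
}
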