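# Study driver: the 5 diameters x 7 stenosis ratios design grid, per-diameter
# cardiac output, and the per-case metric pipeline.

CO_TABLE_LMIN <- c("3" = 2.122, "3.5" = 2.303, "4" = 2.458,
                   "4.5" = 2.630, "5" = 2.798)

#' Cardiac output assigned to a shunt diameter
#'
#' Larger shunts unload more of the cardiac output into the lungs and the
#' ventricle responds with a larger total output; the study uses a fixed
#' per-diameter table (2.122, 2.303, 2.458, 2.630, 2.798 L/min for 3, 3.5, 4,
#' 4.5, 5 mm), independent of the stenosis ratio.
#'
#' @param diameter_mm shunt diameter in mm.
#' @param interpolate if `TRUE`, linearly interpolate between table diameters;
#'   by default unknown diameters are an error.
#' @return Cardiac output (L/min).
#' @export
#' @examples
#' cardiac_output_for_diameter(3)  # 2.122
cardiac_output_for_diameter <- function(diameter_mm, interpolate = FALSE) {
  check_positive(diameter_mm, "diameter_mm")
  key <- format(diameter_mm, trim = TRUE)
  d_tab <- as.numeric(names(CO_TABLE_LMIN))
  idx <- which(abs(d_tab - diameter_mm) < 1e-9)
  if (length(idx) == 1L) return(unname(CO_TABLE_LMIN[idx]))
  if (!interpolate) {
    abort_shuntr("lookup_error",
                 sprintf("no cardiac output tabulated for %g mm (set interpolate = TRUE)",
                         diameter_mm))
  }
  if (diameter_mm < min(d_tab) || diameter_mm > max(d_tab)) {
    abort_shuntr("lookup_error",
                 sprintf("%g mm is outside the tabulated range [%g, %g] mm",
                         diameter_mm, min(d_tab), max(d_tab)))
  }
  stats::approx(d_tab, unname(CO_TABLE_LMIN), xout = diameter_mm)$y
}

#' The design grid of the shunt study
#'
#' @param diameters_mm shunt diameters (mm); default 3, 3.5, 4, 4.5, 5.
#' @param alphas stenosis ratios; default 0, 0.05, ..., 0.30.
#' @param co_table named numeric vector mapping diameter (mm, as names) to
#'   cardiac output (L/min); default the study table.
#' @return A `sweep_grid` object.
#' @export
sweep_grid <- function(diameters_mm = GRID_DIAMETERS_MM,
                       alphas = GRID_ALPHAS,
                       co_table = CO_TABLE_LMIN) {
  if (!length(diameters_mm) || !length(alphas)) {
    abort_shuntr("invalid_argument", "grid axes must be non-empty")
  }
  covered <- vapply(diameters_mm, function(d) {
    any(abs(as.numeric(names(co_table)) - d) < 1e-9)
  }, logical(1))
  if (!all(covered)) {
    abort_shuntr("lookup_error",
                 sprintf("co_table does not cover diameters: %s",
                         paste(diameters_mm[!covered], collapse = ", ")))
  }
  structure(list(diameters_mm = sort(diameters_mm), alphas = sort(alphas),
                 co_table = co_table),
            class = "sweep_grid")
}

#' Run one grid case end to end
#'
#' Assembles the network, solves steady state, and computes all evaluation
#' metrics: flow splits, power loss and relative power loss, shunt Reynolds
#' number, and the oxygen report. Oxygen-infeasible operating points are
#' marked in the `status` field rather than dropped.
#'
#' @param patient a [patient_network()].
#' @param case a [case_definition()].
#' @return A `case_report` list: the case coordinates, `qp_qs`, `q_lpa_rpa`,
#'   `power_loss_mW`, `relative_power_loss_pct`, `reynolds_shunt`, the
#'   `oxygen` report (or `NULL` if infeasible), solver diagnostics and a
#'   `status` string (`"ok"`, `"oxygen_infeasible"`).
#' @export
run_case <- function(patient, case) {
  sol <- tryCatch(
    solve_case(patient, case),
    shuntr_error = function(e) {
      abort_shuntr("solver_error",
                   sprintf("case d = %g mm, alpha = %g failed: %s",
                           case$shunt_diameter * 1e3, case$alpha,
                           conditionMessage(e)))
    }
  )
  splits <- flow_splits(sol)
  pl <- power_loss(sol)
  rpl <- relative_power_loss(sol)
  re_sh <- reynolds_number(sol$element_flows[["shunt"]], case$shunt_diameter,
                           sol$blood)

  status <- "ok"
  oxy <- tryCatch(
    oxygen_report(m3s_to_mlmin(splits$q_p), m3s_to_mlmin(splits$q_s)),
    shuntr_infeasible_oxygen = function(e) {
      status <<- "oxygen_infeasible"
      NULL
    }
  )

  structure(list(
    diameter_mm = case$shunt_diameter * 1e3,
    alpha = case$alpha,
    cardiac_output_lmin = m3s_to_lmin(case$cardiac_output),
    qp_qs = splits$qp_qs,
    q_lpa_rpa = splits$q_lpa_rpa,
    q_p = splits$q_p,
    q_s = splits$q_s,
    power_loss_mW = pl,
    relative_power_loss_pct = rpl,
    reynolds_shunt = re_sh,
    oxygen = oxy,
    mass_residual = sol$residual,
    iterations = sol$iterations,
    shunt_reversed = sol$shunt_reversed,
    status = status,
    solution = sol
  ), class = "case_report")
}

report_row <- function(rep) {
  data.frame(
    diameter_mm = rep$diameter_mm,
    alpha = rep$alpha,
    qp_qs = rep$qp_qs,
    q_lpa_rpa = rep$q_lpa_rpa,
    pl_mW = rep$power_loss_mW,
    rpl_pct = rep$relative_power_loss_pct,
    do2_ml_min = if (is.null(rep$oxygen)) NA_real_ else rep$oxygen$do2,
    cart = if (is.null(rep$oxygen)) NA_real_ else rep$oxygen$c_art,
    cven = if (is.null(rep$oxygen)) NA_real_ else rep$oxygen$c_ven,
    re_shunt = rep$reynolds_shunt,
    co_l_min = rep$cardiac_output_lmin,
    mass_residual = rep$mass_residual,
    iterations = rep$iterations,
    status = rep$status,
    stringsAsFactors = FALSE
  )
}

#' Run the full design grid
#'
#' Executes every (diameter, \eqn{\alpha}) combination in deterministic order
#' (diameter ascending, then \eqn{\alpha} ascending), assigning the tabulated
#' cardiac output per diameter. Failed cases become rows with their grid
#' coordinates and a `status` message; partial results are still returned.
#'
#' @param patient a [patient_network()].
#' @param grid a [sweep_grid()].
#' @param verbose if `TRUE`, print one line per case with residual and
#'   iteration count.
#' @return A data.frame with one row per case and columns `diameter_mm`,
#'   `alpha`, `qp_qs`, `q_lpa_rpa`, `pl_mW`, `rpl_pct`, `do2_ml_min`, `cart`,
#'   `cven`, `re_shunt`, `co_l_min`, `mass_residual`, `iterations`, `status`.
#' @export
#' @examples
#' \donttest{
#' res <- run_grid(reference_patient(), sweep_grid())
#' head(res)
#' }
run_grid <- function(patient, grid = sweep_grid(), verbose = FALSE) {
  if (!inherits(grid, "sweep_grid")) {
    abort_shuntr("invalid_argument", "`grid` must be a sweep_grid")
  }
  rows <- list()
  k <- 0L
  for (d in grid$diameters_mm) {
    co <- cardiac_output_for_diameter(d)
    for (a in grid$alphas) {
      k <- k + 1L
      case <- case_definition(d * 1e-3, a, lmin_to_m3s(co))
      row <- tryCatch({
        rep <- run_case(patient, case)
        if (verbose) {
          message(sprintf("case d=%g mm alpha=%g: residual=%.2e kg/s, %d iterations",
                          d, a, rep$mass_residual, rep$iterations))
        }
        rr <- report_row(rep)
        rr$diameter_mm <- d  # grid value, not the m -> mm float round trip
        rr
      }, shuntr_error = function(e) {
        data.frame(diameter_mm = d, alpha = a, qp_qs = NA_real_,
                   q_lpa_rpa = NA_real_, pl_mW = NA_real_, rpl_pct = NA_real_,
                   do2_ml_min = NA_real_, cart = NA_real_, cven = NA_real_,
                   re_shunt = NA_real_, co_l_min = co, mass_residual = NA_real_,
                   iterations = NA_integer_,
                   status = paste("failed:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep result table to CSV
#'
#' @param results data.frame from [run_grid()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_case_reports <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
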