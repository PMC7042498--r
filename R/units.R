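# Unit conversions. All model internals are SI (Pa, m3/s, kg/m3, Pa.s);
# clinical units (mmHg, L/min, MPa.s.m-3, mL/min) live at the I/O boundary.

#' Unit conversion helpers
#'
#' The solver works in SI units throughout (pressures in Pa, flows in m\eqn{^3}/s,
#' resistances in Pa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}}). Clinical quantities are
#' usually quoted in mmHg, L/min and MPa\eqn{\cdot}s\eqn{\cdot}m\eqn{^{-3}};
#' these helpers convert at the boundary.
#'
#' @param x numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' mmHg_to_Pa(74.33)
#' Pa_to_mmHg(10000)
#' lmin_to_m3s(2.122)
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname units
#' @export
lmin_to_m3s <- function(x) x * 1e-3 / 60

#' @rdname units
#' @export
m3s_to_lmin <- function(x) x * 60 * 1e3

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x * 60 * 1e6

#' @rdname units
#' @export
MPa_s_m3_to_SI <- function(x) x * 1e6

#' @rdname units
#' @export
SI_to_MPa_s_m3 <- function(x) x / 1e6

# typed condition constructor; class is prefixed so callers can catch
# shuntr_<class> specifically or shuntr_error generically
abort_shuntr <- function(class, message, ...) {
  stop(errorCondition(message,
    class = c(paste0("shuntr_", class), "shuntr_error", "error", "condition"),
    ...
  ))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_shuntr("invalid_argument", sprintf("`%s` must be a single positive finite number", what))
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_shuntr("invalid_argument", sprintf("`%s` must be a single non-negative finite number", what))
  }
  invisible(x)
}
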