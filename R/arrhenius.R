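#' Arrhenius parameter pair
#'
#' Bundles a pre-exponential factor and an activation energy. The
#' pre-exponential factor carries the units of the rate coefficient of its
#' channel (L mol^-1 s^-1 for bimolecular steps, s^-1 for unimolecular ones);
#' the activation energy is in J mol^-1.
#'
#' @param A Pre-exponential factor (> 0), in the channel's rate-coefficient
#'   units.
#' @param Ea Activation energy in J mol^-1 (>= 0).
#' @return An object of class `arrhenius`.
#' @examples
#' arrhenius_params(A = 3.8e7, Ea = 6.66e4)
#' @export
arrhenius_params <- function(A, Ea = 0) {
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A <= 0) {
    abort("`A` must be a single positive finite number.")
  }
  if (!is.numeric(Ea) || length(Ea) != 1 || !is.finite(Ea) || Ea < 0) {
    abort("`Ea` must be a single non-negative finite number (J mol^-1).")
  }
  structure(list(A = as.numeric(A), Ea = as.numeric(Ea)), class = "arrhenius")
}

#' @export
print.arrhenius <- function(x, ...) {
  cat(sprintf("<arrhenius> A = %g, Ea = %g J/mol\n", x$A, x$Ea))
  invisible(x)
}

#' Evaluate an Arrhenius rate coefficient
#'
#' Computes `k(T) = A * exp(-Ea / (R * T))` with the gas constant
#' R = 8.314 J mol^-1 K^-1.
#'
#' @param params An [arrhenius_params()] object (or a list with elements
#'   `A` and `Ea`).
#' @param temperature Absolute temperature in kelvin (> 0). May be a vector.
#' @return Rate coefficient(s) in the units of `A`.
#' @examples
#' arrhenius_rate(arrhenius_params(5), 400)            # Ea = 0: returns A
#' arrhenius_rate(arrhenius_params(1e8, 7e4), 413.15)
#' @export
arrhenius_rate <- function(params, temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    abort("`temperature` must be positive and finite (kelvin).")
  }
  if (is.null(params$A) || is.null(params$Ea)) {
    abort("`params` must have elements `A` and `Ea`.")
  }
  params$A * exp(-params$Ea / (.R_GAS * temperature))
}

#' Convert Celsius to kelvin
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
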