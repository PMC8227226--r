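#' Physical constants for electrode-kinetics calculations
#'
#' Bundles the constants used by the Laviron and half-peak-width relations:
#' the gas constant, the Faraday constant, the working temperature, and the
#' 47.7 mV numerator of the irreversible half-peak-width relation at 25 degC.
#'
#' @param temperature_K absolute temperature in kelvin; default 298 K.
#' @return A list with components `R` (8.314 J K^-1 mol^-1), `T` (kelvin),
#'   `F` (96480 C mol^-1) and `bard_faulkner_mv` (47.7 mV).
#' @examples
#' voltammetry_constants()
#' voltammetry_constants(temperature_K = 310)
#' @export
voltammetry_constants <- function(temperature_K = 298) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive finite number")
  }
  list(R = 8.314, T = temperature_K, F = 96480, bard_faulkner_mv = 47.7)
}

check_constants <- function(constants) {
  need <- c("R", "T", "F", "bard_faulkner_mv")
  if (!is.list(constants) || !all(need %in% names(constants))) {
    stop("`constants` must be a list as returned by voltammetry_constants()")
  }
  vals <- unlist(constants[need])
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be strictly positive and finite")
  }
  invisible(constants)
}
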