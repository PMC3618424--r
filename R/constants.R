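# Physical constants (CODATA 2018)
.GAS_CONSTANT <- 8.314462618    # J mol^-1 K^-1
.FARADAY      <- 96485.33212    # C mol^-1

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return RT/F in mV (about 26.73 mV at 37 degrees C).
#' @export
#' @examples
#' thermal_voltage(37)
thermal_voltage <- function(temperature_C = 37) {
  stopifnot(is.numeric(temperature_C), is.finite(temperature_C))
  1000 * .GAS_CONSTANT * (temperature_C + 273.15) / .FARADAY
}
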