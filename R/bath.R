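# Recording-solution composition.
#
# Default internal concentrations: [K+]i = 120 mM (the value assumed for the
# valinomycin calibration), [Na+]i = 14 mM and [Cl-]i = 40 mM, chosen so the
# three-ion forward model reproduces the resting potentials of
# non-capacitated sperm (about -39 mV mutant / -45 mV wild-type at 5 mM
# external K+). Default external concentrations follow the HS medium recipe:
# Na_out = 151 mM (135 NaCl + 1 Na-pyruvate + 15 NaHCO3), Cl_out = 143 mM.

# Nominal 0 mM substitutions (e.g. "1 mM Na" media made with NMDG+ or
# methanesulfonate) are floored here so logarithms stay defined.
.CONC_FLOOR <- 1e-3

#' Define a recording-bath composition
#'
#' Bundles the internal/external K+, Na+ and Cl- concentrations and the
#' temperature that define one recording solution. Concentrations of exactly
#' zero are floored at 1e-3 mM so that logarithmic terms remain defined;
#' negative concentrations are an error.
#'
#' @param K_out,Na_out,Cl_out external concentrations, mM.
#' @param K_in,Na_in,Cl_in internal concentrations, mM.
#' @param temperature_C bath temperature, degrees Celsius, in \[0, 50\].
#' @return An object of class `"bath"`: a named list of the seven fields.
#' @export
#' @examples
#' bath_composition(K_out = 5)
bath_composition <- function(K_out, Na_out = 151, Cl_out = 143,
                             K_in = 120, Na_in = 14, Cl_in = 40,
                             temperature_C = 37) {
  conc <- list(K_out = K_out, Na_out = Na_out, Cl_out = Cl_out,
               K_in = K_in, Na_in = Na_in, Cl_in = Cl_in)
  for (nm in names(conc)) {
    x <- conc[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("concentration '", nm, "' must be a finite number", call. = FALSE)
    if (x < 0)
      stop("concentration '", nm, "' must be positive (got ", x, ")",
           call. = FALSE)
    if (x < .CONC_FLOOR) conc[[nm]] <- .CONC_FLOOR
  }
  if (!is.numeric(temperature_C) || length(temperature_C) != 1L ||
      !is.finite(temperature_C) || temperature_C < 0 || temperature_C > 50)
    stop("temperature_C must lie in [0, 50]", call. = FALSE)
  structure(c(conc, list(temperature_C = temperature_C)), class = "bath")
}

#' @export
print.bath <- function(x, ...) {
  cat("Recording bath (mM, inside / outside):\n")
  cat(sprintf("  K+ : %7.3f / %7.3f\n", x$K_in, x$K_out))
  cat(sprintf("  Na+: %7.3f / %7.3f\n", x$Na_in, x$Na_out))
  cat(sprintf("  Cl-: %7.3f / %7.3f\n", x$Cl_in, x$Cl_out))
  cat(sprintf("  temperature: %.1f C\n", x$temperature_C))
  invisible(x)
}

#' Bath for a named medium at a given external K+
#'
#' Applies the low-Na+ / low-Cl- substitutions of the experimental media
#' (impermeant replacements, modelled as concentration changes only) on top
#' of the standard HS-medium composition.
#'
#' @param K_out external K+, mM.
#' @param media one of `"normal"`, `"low-Na"` (1 mM Na+), `"low-Cl-44"`,
#'   `"low-Cl-5"`.
#' @param ... passed on to [bath_composition()] (e.g. internal overrides).
#' @return A `"bath"` object.
#' @export
media_bath <- function(K_out, media = c("normal", "low-Na", "low-Cl-44",
                                        "low-Cl-5"), ...) {
  media <- match.arg(media)
  args <- switch(media,
    "normal"    = list(),
    "low-Na"    = list(Na_out = 1),
    "low-Cl-44" = list(Cl_out = 44),
    "low-Cl-5"  = list(Cl_out = 5))
  do.call(bath_composition, c(list(K_out = K_out), args, list(...)))
}

# replace the external K+ of a bath (used when sweeping the K grid)
set_K_out <- function(bath, K_out) {
  stopifnot(inherits(bath, "bath"))
  bath_composition(K_out = K_out, Na_out = bath$Na_out, Cl_out = bath$Cl_out,
                   K_in = bath$K_in, Na_in = bath$Na_in, Cl_in = bath$Cl_in,
                   temperature_C = bath$temperature_C)
}
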