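# Nernst and Goldman-Hodgkin-Katz forward models.
#
# Sign convention throughout: membrane potential Em is inside relative to
# outside, in mV. Anion (Cl-) concentration terms in the GHK expression are
# swapped: internal Cl- appears in the numerator, external in the
# denominator.

#' Nernst equilibrium potential
#'
#' `(RT/zF) * ln(C_out / C_in)` in mV, inside minus outside.
#'
#' @param C_in,C_out internal/external concentration, mM; must be > 0.
#' @param valence ion valence z (nonzero integer; -1 for Cl-).
#' @param temperature_C temperature in degrees Celsius.
#' @return Equilibrium potential in mV.
#' @export
#' @examples
#' nernst_potential(C_in = 120, C_out = 5)    # E_K of the calibration, -84.9
nernst_potential <- function(C_in, C_out, valence = 1L, temperature_C = 37) {
  if (!is.numeric(C_in) || anyNA(C_in) || any(C_in <= 0))
    stop("C_in must be > 0", call. = FALSE)
  if (!is.numeric(C_out) || anyNA(C_out) || any(C_out <= 0))
    stop("C_out must be > 0", call. = FALSE)
  if (valence == 0) stop("valence must be nonzero", call. = FALSE)
  thermal_voltage(temperature_C) / valence * log(C_out / C_in)
}

#' GHK membrane potential for K+, Na+ and Cl-
#'
#' Three-ion Goldman-Hodgkin-Katz voltage:
#' `Em = (RT/F) * ln((P_K*K_out + P_Na*Na_out + P_Cl*Cl_in) /
#' (P_K*K_in + P_Na*Na_in + P_Cl*Cl_out))`.
#' Monovalent ions only; divalents are not part of the model.
#'
#' @param perms a [perm_set()] (at least one permeability > 0).
#' @param bath a [bath_composition()].
#' @return Membrane potential in mV.
#' @export
#' @examples
#' b <- bath_composition(K_out = 5)
#' ghk_voltage(perm_set(1.0, 0.13, 0.6), b)   # mutant resting Em, about -39
ghk_voltage <- function(perms, bath) {
  perms <- as_perm_set(perms)
  stopifnot(inherits(bath, "bath"))
  if (sum(perms) <= 0)
    stop("undefined voltage: all permeabilities are zero", call. = FALSE)
  num <- perms[["P_K"]] * bath$K_out + perms[["P_Na"]] * bath$Na_out +
    perms[["P_Cl"]] * bath$Cl_in
  den <- perms[["P_K"]] * bath$K_in + perms[["P_Na"]] * bath$Na_in +
    perms[["P_Cl"]] * bath$Cl_out
  thermal_voltage(bath$temperature_C) * log(num / den)
}

#' Per-ion equilibrium potentials of a bath
#'
#' @param bath a [bath_composition()].
#' @return Named numeric vector `c(E_K, E_Na, E_Cl)` in mV (Cl- computed
#'   with valence -1).
#' @export
equilibrium_potentials <- function(bath) {
  stopifnot(inherits(bath, "bath"))
  tc <- bath$temperature_C
  c(E_K  = nernst_potential(bath$K_in,  bath$K_out,  +1L, tc),
    E_Na = nernst_potential(bath$Na_in, bath$Na_out, +1L, tc),
    E_Cl = nernst_potential(bath$Cl_in, bath$Cl_out, -1L, tc))
}

#' Passive chloride redistribution fixed point
#'
#' When internal Cl- is not actively maintained, a sustained
#' hyperpolarization drives Cl- out of the cell until its equilibrium
#' potential matches the membrane potential. At that fixed point Cl-
#' carries no net flux, so Em is set by the K+ and Na+ terms alone:
#' `Em = (RT/F) * ln((P_K*K_out + P_Na*Na_out)/(P_K*K_in + P_Na*Na_in))`,
#' and the redistributed internal chloride is
#' `Cl_in = Cl_out * exp(Em * F/RT)`. The pair satisfies `E_Cl(Cl_in) = Em`
#' exactly; the residual is reported as a diagnostic.
#'
#' @param perms a [perm_set()] with `P_K + P_Na > 0`.
#' @param bath a [bath_composition()]; its `Cl_in` is ignored (replaced by
#'   the equilibrium value).
#' @return A list with `Em` (mV), `Cl_in` (mM) and `residual`
#'   (`|E_Cl(Cl_in) - Em|`, mV).
#' @export
#' @examples
#' b <- bath_composition(K_out = 5)
#' solve_passive_chloride(perm_set(4.38, 0.13, 0.6), b)  # Cl_in ~ 11 mM
solve_passive_chloride <- function(perms, bath) {
  perms <- as_perm_set(perms)
  stopifnot(inherits(bath, "bath"))
  if (perms[["P_K"]] + perms[["P_Na"]] <= 0)
    stop("P_K + P_Na must be > 0 for a chloride fixed point", call. = FALSE)
  vt <- thermal_voltage(bath$temperature_C)
  num <- perms[["P_K"]] * bath$K_out + perms[["P_Na"]] * bath$Na_out
  den <- perms[["P_K"]] * bath$K_in + perms[["P_Na"]] * bath$Na_in
  Em <- vt * log(num / den)
  Cl_in <- bath$Cl_out * exp(Em / vt)
  residual <- abs(nernst_potential(Cl_in, bath$Cl_out, -1L,
                                   bath$temperature_C) - Em)
  list(Em = Em, Cl_in = Cl_in, residual = residual)
}
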