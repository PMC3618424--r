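# Shared fixtures: the standard bath and the running-text permeability sets.

std_bath <- function(K_out = 5) bath_composition(K_out = K_out)

perms_wt_noncap  <- perm_set(P_K = 1.6,  P_Na = 0.13, P_Cl = 0.6)
perms_mut_noncap <- perm_set(P_K = 1.0,  P_Na = 0.13, P_Cl = 0.6)
perms_wt_cap     <- perm_set(P_K = 4.38, P_Na = 0.13, P_Cl = 0.6)

# calibration K+ concentrations: 5 mM plus doubling KCl aliquots
cal_steps <- c(5, 7.25, 11.75, 20.75, 38.75)

# build an Em table directly from a permeability set (noise-free)
exact_table <- function(perms, K_grid = c(5, 10, 20, 30), sem = NA_real_,
                        bath = std_bath(), condition = NULL) {
  em <- vapply(K_grid, function(k) ghk_voltage(perms, set_K_out_(bath, k)),
               numeric(1))
  em_table(K_grid, em, Em_sem = sem, n = if (is.na(sem[1])) 1L else 11L,
           condition = condition)
}

# numerical dEm/dK_out of a fitted model, written independently of the
# package's own slope helper
em_slope_ <- function(fit, K_out, h = 1e-3) {
  p <- fit$perms
  emk <- function(k) ghk_voltage(p, set_K_out_(fit$bath_template, k))
  (emk(K_out + h) - emk(K_out - h)) / (2 * h)
}

# local copy of the internal K_out-swap helper (tests run against the
# installed namespace)
set_K_out_ <- function(bath, K_out) {
  bath_composition(K_out = K_out, Na_out = bath$Na_out, Cl_out = bath$Cl_out,
                   K_in = bath$K_in, Na_in = bath$Na_in, Cl_in = bath$Cl_in,
                   temperature_C = bath$temperature_C)
}
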