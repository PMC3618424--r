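# Nernst/GHK forward models and the passive-chloride fixed point.

test_that("Nernst potential matches the valinomycin calibration anchors", {
  # printed one-decimal values from the population assay (K_in = 120, 37 C)
  expect_equal(nernst_potential(120, 5), -84.9, tolerance = 0.002)
  expect_equal(nernst_potential(120, 38.75), -30.2, tolerance = 0.002)
  # equal concentrations give zero for any valence
  expect_equal(nernst_potential(42, 42, valence = 1L), 0)
  expect_equal(nernst_potential(42, 42, valence = -2L), 0)
  # sign flips with valence
  expect_equal(nernst_potential(40, 143, valence = -1L),
               -nernst_potential(40, 143, valence = 1L))
})

test_that("Nernst potential rejects bad inputs naming the field", {
  expect_error(nernst_potential(0, 5), "C_in")
  expect_error(nernst_potential(120, -1), "C_out")
  expect_error(nernst_potential(120, 5, valence = 0), "valence")
})

test_that("GHK reduces to the single-ion Nernst potential", {
  baths <- list(std_bath(5), std_bath(30),
                bath_composition(K_out = 10, Na_out = 1, Cl_out = 44,
                                 temperature_C = 25))
  for (b in baths) {
    expect_equal(ghk_voltage(perm_set(2.5, 0, 0), b),
                 nernst_potential(b$K_in, b$K_out, 1L, b$temperature_C),
                 tolerance = 1e-9)
    expect_equal(ghk_voltage(perm_set(0, 0.4, 0), b),
                 nernst_potential(b$Na_in, b$Na_out, 1L, b$temperature_C),
                 tolerance = 1e-9)
    expect_equal(ghk_voltage(perm_set(0, 0, 1.1), b),
                 nernst_potential(b$Cl_in, b$Cl_out, -1L, b$temperature_C),
                 tolerance = 1e-9)
  }
})

test_that("GHK voltage is invariant under uniform permeability scaling", {
  b <- std_bath(5)
  base <- ghk_voltage(perms_wt_noncap, b)
  for (c in c(1e-3, 0.1, 3, 250)) {
    scaled <- perm_set(1.6 * c, 0.13 * c, 0.6 * c)
    expect_equal(ghk_voltage(scaled, b), base, tolerance = 1e-9)
  }
})

test_that("GHK voltage is strictly increasing in external K+", {
  ks <- seq(2, 60, by = 2)
  for (p in list(perms_mut_noncap, perms_wt_cap, perm_set(1, 0, 0))) {
    em <- vapply(ks, function(k) ghk_voltage(p, std_bath(k)), numeric(1))
    expect_true(all(diff(em) > 0))
  }
})

test_that("GHK voltage lies between the extreme per-ion Nernst potentials", {
  set.seed(7)
  b <- std_bath(5)
  eq <- equilibrium_potentials(b)
  for (i in 1:50) {
    p <- perm_set(runif(1, 0.01, 10), runif(1, 0.01, 10),
                  runif(1, 0.01, 10))
    em <- ghk_voltage(p, b)
    expect_gt(em, min(eq)); expect_lt(em, max(eq))
  }
})

test_that("resting potentials reproduce from the printed permeabilities", {
  b <- std_bath(5)
  expect_equal(ghk_voltage(perms_mut_noncap, b), -39, tolerance = 0.01)
  expect_equal(ghk_voltage(perms_wt_noncap, b), -45, tolerance = 0.01)
  expect_error(ghk_voltage(perm_set(0, 0, 0), b), "all permeabilities")
})

test_that("equilibrium potentials carry the right signs and anchors", {
  b <- std_bath(5)
  eq <- equilibrium_potentials(b)
  expect_equal(unname(eq["E_K"]), -84.9, tolerance = 0.002)
  # E_Cl = (RT/F) ln(Cl_in/Cl_out): direct evaluation
  expect_equal(unname(eq["E_Cl"]),
               thermal_voltage(37) * log(40 / 143), tolerance = 1e-9)
  expect_gt(unname(eq["E_Na"]), 0)  # Na+ gradient is inward
  sym <- bath_composition(K_out = 10, Na_out = 10, Cl_out = 10,
                          K_in = 10, Na_in = 10, Cl_in = 10)
  expect_equal(unname(equilibrium_potentials(sym)), c(0, 0, 0))
})

test_that("passive chloride fixed point satisfies E_Cl(Cl_in) = Em", {
  b <- std_bath(5)
  sol <- solve_passive_chloride(perms_wt_cap, b)
  expect_lt(sol$residual, 1e-6)
  # capacitated wild-type prediction: internal Cl- falls to ~10-12 mM
  expect_gte(sol$Cl_in, 9); expect_lte(sol$Cl_in, 12)
  # P_Na = 0: closed form Em = E_K, Cl_in = Cl_out * exp(E_K F/RT)
  sol0 <- solve_passive_chloride(perm_set(1, 0, 0.6), b)
  ek <- unname(equilibrium_potentials(b)["E_K"])
  expect_equal(sol0$Em, ek, tolerance = 1e-9)
  expect_equal(sol0$Cl_in, b$Cl_out * exp(ek / thermal_voltage(37)),
               tolerance = 1e-9)
  # zero-potential bath: Cl_in equals Cl_out
  symb <- bath_composition(K_out = 120, Na_out = 14, Cl_out = 143,
                           K_in = 120, Na_in = 14, Cl_in = 143)
  expect_equal(solve_passive_chloride(perm_set(1, 1, 0), symb)$Cl_in,
               symb$Cl_out, tolerance = 1e-9)
  expect_error(solve_passive_chloride(perm_set(0, 0, 1), b), "P_K \\+ P_Na")
})

test_that("bath validation floors zeros and rejects bad temperature", {
  b <- media_bath(5, media = "low-Na")
  expect_equal(b$Na_out, 1)
  floored <- bath_composition(K_out = 5, Na_out = 0)
  expect_equal(floored$Na_out, 1e-3)
  expect_error(bath_composition(K_out = -5), "K_out")
  expect_error(bath_composition(K_out = 5, temperature_C = 80),
               "temperature")
})
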