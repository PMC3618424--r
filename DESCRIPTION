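Package: ghkperm
Title: Relative Ion Permeabilities from Membrane Potential Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates relative K+, Na+ and Cl- membrane permeabilities from
    population membrane-potential measurements at several external K+
    concentrations, as done in potentiometric-dye studies of mouse sperm
    capacitation. Provides Nernst and Goldman-Hodgkin-Katz (GHK) forward
    models, valinomycin/KCl-step calibration of fluorescence traces to
    millivolts, staged constrained GHK least-squares fitting across
    genotypes and conditions, a passive-chloride redistribution solver,
    chi-square curve comparison, and a synthetic-data generator that
    emulates the fluorimetry experiments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
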