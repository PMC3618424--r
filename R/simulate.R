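# Synthetic-data generator emulating the population fluorimetry
# experiments: Em-vs-[K+]e tables with Gaussian replicate noise, and
# DiSC3-(5)-style traces with a valinomycin/KCl-step calibration tail.

# evaluate code with a locally-set RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults reproduce the study conditions: external K+ grid 5/10/20/30 mM,
#' n = 11 replicates, replicate noise sigma = 2 mV (the few-mV SEM scale of
#' the population measurements), and a positive-gain affine dye model
#' (fluorescence falls upon hyperpolarization).
#'
#' @param K_grid external K+ concentrations for Em tables, mM.
#' @param n replicates per K+ concentration.
#' @param sigma replicate noise standard deviation, mV.
#' @param seed RNG seed recorded in all outputs (`NULL` to use the current
#'   RNG state).
#' @param cal_K_steps cumulative K+ after each calibration KCl aliquot, mM
#'   (defaults to doubling aliquots into 5 mM: 7.25, 11.75, 20.75, 38.75).
#' @param dye_gain dye slope dF/dEm, AU/mV (must be > 0).
#' @param dye_offset dye offset, AU.
#' @param dye_sigma fluorescence noise standard deviation, AU.
#' @param dt trace sampling interval, s.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(K_grid = c(5, 10, 20, 30), n = 11, sigma = 2,
                             seed = 1, cal_K_steps = .CAL_K_STEPS,
                             dye_gain = 5, dye_offset = 600, dye_sigma = 5,
                             dt = 1) {
  stopifnot(all(K_grid > 0), n >= 1, sigma >= 0, dye_sigma >= 0,
            dye_gain > 0, dt > 0)
  structure(list(K_grid = sort(K_grid), n = as.integer(n), sigma = sigma,
                 seed = seed, cal_K_steps = cal_K_steps, dye_gain = dye_gain,
                 dye_offset = dye_offset, dye_sigma = dye_sigma, dt = dt),
            class = "generator_config")
}

# noiseless population-mean Em for a condition at one K_out:
# mixture-weighted mean of the subpopulation voltages. In low-Cl- media
# internal Cl- is not actively maintained and redistributes passively, so
# the generator replaces Cl_in by its fixed-point value there (which makes
# the Em-vs-K+ relation steeper, as observed experimentally).
true_em <- function(spec, K_out, registry = preset_registry()) {
  perms <- preset_permeabilities(spec, registry)
  b <- condition_bath(spec, K_out = K_out)
  if (spec$media %in% c("low-Cl-44", "low-Cl-5")) {
    cl <- solve_passive_chloride(perms, b)$Cl_in
    b <- bath_composition(K_out = b$K_out, Na_out = b$Na_out,
                          Cl_out = b$Cl_out, K_in = b$K_in, Na_in = b$Na_in,
                          Cl_in = cl, temperature_C = b$temperature_C)
  }
  base <- ghk_voltage(perms, b)
  f <- spec$mixed_fraction
  if (f > 0) {
    v <- base + spec$subpop_offsets
    f * v[1] + (1 - f) * v[2]
  } else base
}

#' Simulate an Em-vs-\[K+\]e table
#'
#' For each external K+ on the grid, the true membrane potential is the GHK
#' voltage of the condition's preset permeabilities (population-weighted if
#' the condition declares a mixed population); `n` Gaussian replicates with
#' standard deviation `sigma` are drawn and summarized as mean/SEM/n.
#' Deterministic given the seed.
#'
#' @param spec a [condition_spec()].
#' @param cfg a [generator_config()].
#' @param registry condition-preset registry.
#' @return An [em_table()] carrying the condition and seed as attributes.
#' @export
#' @examples
#' simulate_em_table(condition_spec("SLO3-mutant", "non-capacitated"),
#'                   generator_config(seed = 1))
simulate_em_table <- function(spec, cfg = generator_config(),
                              registry = preset_registry()) {
  stopifnot(inherits(spec, "condition_spec"),
            inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    rows <- lapply(cfg$K_grid, function(k) {
      mu <- true_em(spec, k, registry)
      reps <- mu + stats::rnorm(cfg$n, 0, cfg$sigma)
      data.frame(K_out = k, Em_mean = mean(reps),
                 Em_sem = if (cfg$n > 1) stats::sd(reps) / sqrt(cfg$n)
                          else NA_real_,
                 n = cfg$n)
    })
    d <- do.call(rbind, rows)
    out <- em_table(d$K_out, d$Em_mean, d$Em_sem, d$n, condition = spec)
    attr(out, "seed") <- cfg$seed
    out
  })
}

#' Simulate a potentiometric-dye trace with calibration tail
#'
#' The trace holds a steady-state segment at the condition's true membrane
#' potential, then a valinomycin addition clamping Em to E_K, then
#' sequential KCl steps whose plateaus sit at the corresponding Nernst
#' voltages. Voltages map to arbitrary units through the affine dye model
#' `F = dye_offset + dye_gain * Em` plus Gaussian noise; the positive gain
#' makes fluorescence fall upon hyperpolarization. Deterministic given the
#' seed.
#'
#' @inheritParams simulate_em_table
#' @param segment_s duration of each segment, s.
#' @return A [fluor_trace()]; the generating voltage is stored in the
#'   `"true_Em"` attribute.
#' @export
simulate_fluorescence_trace <- function(spec, cfg = generator_config(),
                                        registry = preset_registry(),
                                        segment_s = 60) {
  stopifnot(inherits(spec, "condition_spec"),
            inherits(cfg, "generator_config"))
  K0 <- 5
  bath0 <- condition_bath(spec, K_out = K0)
  em0 <- true_em(spec, K0, registry)
  anchor_em <- theoretical_calibration_voltages(
    c(K0, cfg$cal_K_steps), K_in = bath0$K_in,
    temperature_C = bath0$temperature_C)
  # segment voltages: resting, valinomycin clamp at E_K(K0), then each step
  seg_em <- c(em0, anchor_em[1], anchor_em[-1])
  n_seg <- length(seg_em)
  seg_start <- (seq_len(n_seg) - 1) * segment_s
  with_seed(cfg$seed, {
    time <- seq(0, n_seg * segment_s - cfg$dt, by = cfg$dt)
    seg_of <- findInterval(time, seg_start)
    em_t <- seg_em[seg_of]
    F <- cfg$dye_offset + cfg$dye_gain * em_t +
      stats::rnorm(length(time), 0, cfg$dye_sigma)
    events <- data.frame(
      time_s = seg_start[-1],
      label = c("valinomycin",
                paste0("KCl to ", cfg$cal_K_steps, " mM")),
      K_out_after = c(K0, cfg$cal_K_steps))
    tr <- fluor_trace(time, F, events, condition = spec)
    attr(tr, "true_Em") <- em0
    attr(tr, "seed") <- cfg$seed
    tr
  })
}
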