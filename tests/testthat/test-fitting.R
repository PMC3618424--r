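# Constrained GHK least-squares fitting.

test_that("noiseless tables are recovered exactly with P_K fixed", {
  tab <- exact_table(perms_mut_noncap)
  fit <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  expect_equal(fit$perms[["P_Na"]], 0.13, tolerance = 1e-6)
  expect_equal(fit$perms[["P_Cl"]], 0.6, tolerance = 1e-6)
  expect_identical(fit$perms[["P_K"]], 1)      # fixed, to machine precision
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$dof, 2)
})

test_that("fits are invariant to uniform rescaling of the generating set", {
  scaled <- perm_set(1.0 * 7, 0.13 * 7, 0.6 * 7)
  tab <- exact_table(scaled)
  fit <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  # normalized to P_K = 1 the same ratios come back
  expect_equal(fit$perms[["P_Na"]], 0.13, tolerance = 1e-6)
  expect_equal(fit$perms[["P_Cl"]], 0.6, tolerance = 1e-6)
})

test_that("SEM weighting and input validation are enforced", {
  tab <- exact_table(perms_mut_noncap, sem = c(1, 2, 2, 3))
  fit <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  expect_equal(fit$weights, 1 / c(1, 2, 2, 3)^2)
  short <- em_table(c(5, 10), c(-39, -35))
  expect_error(fit_ghk(short, std_bath(), constraint_set(P_K = 1)),
               "at least 3")
  expect_error(constraint_set(P_K = 1, P_Na = 0.1, P_Cl = 0.6),
               "no free parameters")
  expect_warning(constraint_set(), "ratios")
})

test_that("grid-search oracle agrees with the optimizer on 3-point tables", {
  # brute-force oracle written directly from the GHK formula
  vt <- 1000 * 8.314462618 * 310.15 / 96485.33212
  K <- c(5, 10, 30)
  withr::with_seed(5, {
    obs <- vapply(K, function(k)
      vt * log((k + 0.13 * 151 + 0.6 * 40) /
                 (120 + 0.13 * 14 + 0.6 * 143)), numeric(1)) + rnorm(3, 0, 1)
  })
  grid <- expand.grid(P_Na = seq(0, 0.5, by = 0.005),
                      P_Cl = seq(0, 1.5, by = 0.005))
  sse <- rep(0, nrow(grid))
  for (i in seq_along(K)) {
    pred <- vt * log((K[i] + grid$P_Na * 151 + grid$P_Cl * 40) /
                       (120 + grid$P_Na * 14 + grid$P_Cl * 143))
    sse <- sse + (obs[i] - pred)^2
  }
  oracle <- grid[which.min(sse), ]
  tab <- em_table(K, obs)
  fit <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  expect_lt(abs(fit$perms[["P_Na"]] - oracle$P_Na), 0.005 + 1e-9)
  expect_lt(abs(fit$perms[["P_Cl"]] - oracle$P_Cl), 0.005 + 1e-9)
})

test_that("parameter recovery attains the design's information floor", {
  # 200 simulated study replicates: sigma = 2 mV, n = 11, K 5/10/20/30
  spec_m <- condition_spec("SLO3-mutant", "non-capacitated")
  spec_w <- condition_spec("wild-type", "non-capacitated")
  bt <- std_bath()
  est <- t(vapply(1:200, function(i) {
    cfg <- generator_config(seed = 20000 + i)
    f1 <- fit_ghk(simulate_em_table(spec_m, cfg), bt,
                  constraint_set(P_K = 1))
    f2 <- fit_ghk(simulate_em_table(spec_w, cfg), bt,
                  constraint_set(P_Na = f1$perms[["P_Na"]],
                                 P_Cl = f1$perms[["P_Cl"]]))
    c(P_Na = f1$perms[["P_Na"]], P_Cl = f1$perms[["P_Cl"]],
      P_K = f2$perms[["P_K"]])
  }, numeric(3)))
  truth <- c(P_Na = 0.13, P_Cl = 0.6, P_K = 1.6)
  mae <- apply(abs(sweep(est, 2, truth)), 2, median)
  bias <- abs(colMeans(est) - truth)
  # P_Na and P_K carry enough information for <10% median error
  expect_lt(mae[["P_Na"]], 0.1 * truth[["P_Na"]])
  expect_lt(mae[["P_K"]], 0.1 * truth[["P_K"]])
  # P_Cl is information-limited by the 4-point design: compare the observed
  # error to the linearized (Fisher) floor computed from the design itself
  vt <- 1000 * 8.314462618 * 310.15 / 96485.33212
  emf <- function(pna, pcl) vapply(c(5, 10, 20, 30), function(k)
    vt * log((k + pna * 151 + pcl * 40) /
               (120 + pna * 14 + pcl * 143)), numeric(1))
  h <- 1e-6
  J <- cbind((emf(0.13 + h, 0.6) - emf(0.13 - h, 0.6)) / (2 * h),
             (emf(0.13, 0.6 + h) - emf(0.13, 0.6 - h)) / (2 * h))
  se_floor <- sqrt(diag((2 / sqrt(11))^2 * solve(t(J) %*% J)))
  expect_lt(mae[["P_Cl"]], 1.3 * 0.674 * se_floor[2])
  # estimates are essentially unbiased
  expect_lt(bias[["P_Na"]], 0.05 * truth[["P_Na"]])
  expect_lt(bias[["P_Cl"]], 0.05 * truth[["P_Cl"]])
  expect_lt(bias[["P_K"]], 0.05 * truth[["P_K"]])
})

test_that("omitting chloride degrades the fit on normal-chloride data", {
  cfg <- generator_config(seed = 41)
  tab <- simulate_em_table(condition_spec("SLO3-mutant", "non-capacitated"),
                           cfg)
  full <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  nocl <- fit_ghk_no_chloride(tab, std_bath(), constraint_set(P_K = 1))
  expect_identical(nocl$perms[["P_Cl"]], 0)
  expect_gt(nocl$sse, full$sse)
  # chloride buffers the voltage: the full model's Em is less sensitive
  # to external K+ than the chloride-free model fitted to the same data
  expect_lt(em_slope_(full, 5), em_slope_(nocl, 5))
})

test_that("chloride-free and full fits agree when the data have no P_Cl", {
  tab <- exact_table(perm_set(1, 0.13, 0))
  full <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  nocl <- fit_ghk_no_chloride(tab, std_bath(), constraint_set(P_K = 1))
  expect_equal(full$perms[["P_Cl"]], 0, tolerance = 1e-6)
  expect_equal(full$perms[["P_Na"]], nocl$perms[["P_Na"]], tolerance = 1e-6)
  expect_equal(full$sse, nocl$sse, tolerance = 1e-6)
})

test_that("low external chloride makes the chloride-free fit adequate", {
  # wild-type non-capacitated cells in 44 and 5 mM external Cl-
  for (media in c("low-Cl-44", "low-Cl-5")) {
    spec <- condition_spec("wild-type", "non-capacitated", media = media)
    tab <- simulate_em_table(spec, generator_config(seed = 43))
    bath <- condition_bath(spec, K_out = 5)
    full <- fit_ghk(tab, bath, constraint_set(P_K = 1.6))
    nocl <- fit_ghk_no_chloride(tab, bath, constraint_set(P_K = 1.6))
    expect_lt(nocl$sse / full$sse, 1.5)
  }
})

test_that("staged fit recovers the condition presets without noise", {
  cfg0 <- generator_config(sigma = 0, n = 1)
  sim <- function(...) simulate_em_table(condition_spec(...), cfg0)
  others <- list(
    wt_cap = sim("wild-type", "capacitated"),
    wt_pH8 = sim("wild-type", "non-capacitated", pH = "8"),
    wt_amiloride = sim("wild-type", "non-capacitated",
                       blocker = "amiloride"))
  fits <- staged_fit(sim("SLO3-mutant", "non-capacitated"),
                     sim("wild-type", "non-capacitated"),
                     other_conditions = others)
  expect_s3_class(fits, "ghk_staged")
  expect_equal(fits$wildtype_baseline$perms[["P_K"]], 1.6,
               tolerance = 1e-6)
  expect_equal(fits$wt_cap$perms[["P_K"]], 4.38, tolerance = 1e-6)
  expect_equal(fits$wt_pH8$perms[["P_K"]], 8.2, tolerance = 1e-6)
  expect_equal(fits$wt_amiloride$perms[["P_Na"]], 0.13 / 6.5,
               tolerance = 1e-4)
  expect_error(staged_fit(sim("SLO3-mutant", "non-capacitated")),
               "baseline")
})

test_that("chi-square curve comparison behaves at its closed-form anchors", {
  tab <- exact_table(perms_mut_noncap, sem = rep(1.5, 4))
  same <- compare_curves_chisq(tab, tab)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # offset by 10 sem at every point: X^2 = 4 * 10^2/2 = 200, p tiny
  off <- em_table(tab$K_out, tab$Em_mean + 10 * 1.5, tab$Em_sem, tab$n)
  big <- compare_curves_chisq(tab, off)
  expect_equal(unname(big$statistic), 4 * 100 / 2, tolerance = 1e-9)
  expect_lt(big$p.value, 1e-6)
  expect_equal(big$p.value,
               pchisq(unname(big$statistic), 4, lower.tail = FALSE))
  # mismatched grids are a usage error
  other <- em_table(c(5, 10, 20), c(-40, -38, -33), rep(1, 3), 4)
  expect_error(compare_curves_chisq(tab, other), "grid")
})

test_that("wild-type vs mutant non-capacitated curves differ significantly", {
  cfg <- generator_config(seed = 1)
  wt <- simulate_em_table(condition_spec("wild-type", "non-capacitated"),
                          cfg)
  mu <- simulate_em_table(condition_spec("SLO3-mutant", "non-capacitated"),
                          generator_config(seed = 2))
  expect_lte(compare_curves_chisq(wt, mu)$p.value, 0.05)
})

test_that("nested-fit p-values flag contributing ions", {
  tab <- simulate_em_table(condition_spec("SLO3-mutant", "non-capacitated"),
                           generator_config(seed = 47))
  fit <- fit_ghk(tab, std_bath(), constraint_set(P_K = 1))
  pv <- permeability_pvalues(fit)
  expect_lt(pv[["P_Na"]], 0.01)   # Na+ term is essential
  expect_lt(pv[["P_K"]], 1e-6)
  expect_true(all(pv >= 0 & pv <= 1, na.rm = TRUE))
})
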