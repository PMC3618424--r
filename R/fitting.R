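# Constrained GHK least-squares fitting of Em-vs-[K+]e tables.
#
# The objective is the SEM-weighted sum of squared residuals between the
# observed mean potentials and the GHK forward voltage, minimized over the
# free permeabilities (box-constrained at zero) with
# Levenberg-Marquardt (minpack.lm::nls.lm) from several deterministic
# log-spaced starts, because the objective can be shallow in P_Na.

.PARAMS <- c("P_K", "P_Na", "P_Cl")

#' Constraint set for a GHK fit
#'
#' Each permeability is either fixed at a numeric value or free (`NA`).
#' Since only permeability ratios are identifiable from voltage data, at
#' least one parameter is normally fixed; an all-free set is allowed for
#' goodness-of-fit checks but triggers an identifiability warning.
#'
#' @param P_K,P_Na,P_Cl numeric to fix the parameter at that value, `NA`
#'   to leave it free.
#' @return An object of class `"ghk_constraints"`.
#' @export
#' @examples
#' constraint_set(P_K = 1)        # mutant baseline: fit P_Na and P_Cl
constraint_set <- function(P_K = NA_real_, P_Na = NA_real_,
                           P_Cl = NA_real_) {
  v <- c(P_K = as.numeric(P_K), P_Na = as.numeric(P_Na),
         P_Cl = as.numeric(P_Cl))
  fixed <- !is.na(v)
  if (any(v[fixed] < 0))
    stop("fixed permeabilities must be >= 0", call. = FALSE)
  if (!any(fixed))
    warning("all permeabilities free: only ratios are identifiable from ",
            "voltage data", call. = FALSE)
  if (all(fixed))
    stop("no free parameters to fit", call. = FALSE)
  structure(list(values = v, fixed = fixed), class = "ghk_constraints")
}

#' @export
print.ghk_constraints <- function(x, ...) {
  s <- ifelse(x$fixed, paste0("fixed at ", signif(x$values, 4)), "free")
  cat("Constraints:", paste(.PARAMS, s, sep = " ", collapse = "; "), "\n")
  invisible(x)
}

# assemble the full parameter vector from free values + constraints
.full_params <- function(free_values, constraints) {
  v <- constraints$values
  v[!constraints$fixed] <- free_values
  v
}

# per-row model voltages; optionally replaces Cl_in by its passive
# redistribution value for each candidate parameter vector
.model_em <- function(params, K_out, bath_template, redistribute_cl) {
  vapply(K_out, function(k) {
    b <- set_K_out(bath_template, k)
    if (redistribute_cl && (params[["P_K"]] + params[["P_Na"]]) > 0) {
      cl <- solve_passive_chloride(perm_set(params[["P_K"]], params[["P_Na"]],
                                            params[["P_Cl"]]), b)$Cl_in
      b <- bath_composition(K_out = b$K_out, Na_out = b$Na_out,
                            Cl_out = b$Cl_out, K_in = b$K_in,
                            Na_in = b$Na_in, Cl_in = cl,
                            temperature_C = b$temperature_C)
    }
    ghk_voltage(perm_set(params[["P_K"]], params[["P_Na"]],
                         params[["P_Cl"]]), b)
  }, numeric(1))
}

#' Fit the GHK model to a membrane-potential table
#'
#' Minimizes `sum_k w_k * (Em_obs(k) - Em_GHK(perms, bath(k)))^2` over the
#' free permeabilities, with `w_k = 1/sem_k^2` when SEMs are available
#' (unit weights otherwise) and all permeabilities bounded below at zero.
#' Five deterministic log-spaced starting points spanning \[0.01, 20\] are
#' tried and the best optimum kept.
#'
#' @param table an [em_table()] with at least 3 distinct K+ concentrations.
#' @param bath_template a [bath_composition()] supplying every
#'   concentration except `K_out`, which is taken per table row.
#' @param constraints a [constraint_set()].
#' @param redistribute_cl if `TRUE`, internal Cl- is replaced by its
#'   passive-redistribution value (from [solve_passive_chloride()]) for
#'   every candidate parameter vector; default off.
#' @param n_starts number of multi-start points.
#' @return An object of class `"ghk_fit"`: permeability estimates
#'   (`perms`), per-row residuals (mV), weighted `sse`, residual degrees
#'   of freedom `dof`, the constraint set, and convergence diagnostics.
#' @export
#' @examples
#' spec <- condition_spec("SLO3-mutant", "non-capacitated")
#' tab <- simulate_em_table(spec, generator_config(sigma = 0, n = 1))
#' fit_ghk(tab, bath_composition(K_out = 5), constraint_set(P_K = 1))
fit_ghk <- function(table, bath_template, constraints,
                    redistribute_cl = FALSE, n_starts = 5) {
  stopifnot(inherits(table, "em_table"), inherits(bath_template, "bath"),
            inherits(constraints, "ghk_constraints"))
  if (length(unique(table$K_out)) < 3L)
    stop("need at least 3 distinct K_out values for a fit", call. = FALSE)
  n_free <- sum(!constraints$fixed)

  w <- if (all(is.finite(table$Em_sem)) && all(table$Em_sem > 0))
    1 / table$Em_sem^2 else rep(1, nrow(table))
  sw <- sqrt(w)

  resid_fn <- function(free_values) {
    p <- .full_params(free_values, constraints)
    # the all-zero boundary has no defined voltage: steer the optimizer
    # away with a large finite residual instead of erroring
    if (sum(p) <= 0) return(sw * 1e6)
    r <- sw * (table$Em_mean - .model_em(p, table$K_out, bath_template,
                                         redistribute_cl))
    r[!is.finite(r)] <- 1e6
    r
  }

  starts <- 10^seq(log10(0.01), log10(20), length.out = n_starts)
  best <- NULL
  last <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = rep(s, n_free), fn = resid_fn,
                         lower = rep(0, n_free),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
    if (inherits(fit, "error")) next
    last <- fit
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("GHK fit failed to converge from any start",
         if (!is.null(last)) paste0("; last iterate: ",
                                    paste(signif(last$par, 4),
                                          collapse = ", ")),
         call. = FALSE)

  params <- .full_params(best$par, constraints)
  pred <- .model_em(params, table$K_out, bath_template, redistribute_cl)
  residuals <- stats::setNames(table$Em_mean - pred,
                               paste0("K", table$K_out))
  structure(list(
    perms = perm_set(params[["P_K"]], params[["P_Na"]], params[["P_Cl"]]),
    residuals = residuals,
    fitted = stats::setNames(pred, paste0("K", table$K_out)),
    sse = sum(w * (table$Em_mean - pred)^2),
    dof = nrow(table) - n_free,
    weights = w,
    constraints = constraints,
    redistribute_cl = redistribute_cl,
    converged = best$info %in% 1:4,
    niter = best$niter,
    message = best$message,
    table = table,
    bath_template = bath_template),
    class = "ghk_fit")
}

#' @export
print.ghk_fit <- function(x, digits = 3, ...) {
  cond <- attr(x$table, "condition")
  cat("GHK fit", if (!is.null(cond)) paste0(" [", condition_label(cond), "]"),
      "\n", sep = "")
  print(x$perms, digits = digits)
  fixed <- .PARAMS[x$constraints$fixed]
  if (length(fixed)) cat("  fixed:", paste(fixed, collapse = ", "), "\n")
  cat(sprintf("  weighted SSE %.4g on %d residual dof%s\n", x$sse, x$dof,
              if (x$redistribute_cl) " (passive Cl- redistribution)" else ""))
  invisible(x)
}

#' GHK fit omitting chloride
#'
#' Identical objective with `P_Cl` fixed at 0 — the "steeper" fit used to
#' show that a resting chloride permeability is required to explain the
#' shallow Em-vs-K+ relation in normal-chloride media.
#'
#' @inheritParams fit_ghk
#' @return A `"ghk_fit"`.
#' @export
fit_ghk_no_chloride <- function(table, bath_template, constraints,
                                redistribute_cl = FALSE, n_starts = 5) {
  v <- constraints$values
  nc <- constraint_set(P_K = v[["P_K"]], P_Na = v[["P_Na"]], P_Cl = 0)
  fit_ghk(table, bath_template, nc, redistribute_cl = redistribute_cl,
          n_starts = n_starts)
}

# numerical dEm/dK_out of a fitted model at a given K_out (mV per mM);
# used for the chloride voltage-buffering comparison
em_slope <- function(fit, K_out = 5, h = 1e-3) {
  p <- unclass(fit$perms)
  up <- .model_em(p, K_out + h, fit$bath_template, fit$redistribute_cl)
  dn <- .model_em(p, K_out - h, fit$bath_template, fit$redistribute_cl)
  (up - dn) / (2 * h)
}

#' Staged fitting across genotypes and conditions
#'
#' Stage 1 fits the non-capacitated SLO3-mutant table with the residual
#' `P_K` fixed at 1.0, solving for `P_Na` and `P_Cl` (the normalization
#' reference: all other permeabilities are relative to this `P_K`).
#' Stage 2 fixes `P_Na`/`P_Cl` at the stage-1 estimates and fits the
#' wild-type `P_K`. Stage 3 fits each remaining condition with
#' condition-appropriate constraints: amiloride (or low-Na) conditions fix
#' `P_K` at the genotype baseline and `P_Cl` at stage 1 and free `P_Na`;
#' all other conditions (capacitated, pH 8, SLO3 blockers) hold
#' `P_Na`/`P_Cl` at stage 1 and free `P_K`. An `"all-free"` mode floats
#' all three permeabilities for goodness-of-fit comparison.
#'
#' @param noncap_mutant,noncap_wildtype non-capacitated baseline
#'   [em_table()]s.
#' @param other_conditions named list of further `em_table`s; each table's
#'   `condition` attribute (a [condition_spec()]) drives its constraint
#'   policy, and its media substitution is applied to the bath.
#' @param bath_template bath for the baselines; per-condition media
#'   substitutions are derived from each table's condition.
#' @param stage3 `"policy"` (the constraint policy above) or `"all-free"`.
#' @param redistribute_cl passed to [fit_ghk()] for stage-3 fits.
#' @return A named list of `"ghk_fit"` objects (class `"ghk_staged"`),
#'   starting with `mutant_baseline` and `wildtype_baseline`.
#' @export
staged_fit <- function(noncap_mutant, noncap_wildtype,
                       other_conditions = list(),
                       bath_template = bath_composition(K_out = 5),
                       stage3 = c("policy", "all-free"),
                       redistribute_cl = FALSE) {
  stage3 <- match.arg(stage3)
  if (missing(noncap_mutant) || missing(noncap_wildtype))
    stop("both non-capacitated baseline tables are required", call. = FALSE)

  fit1 <- fit_ghk(noncap_mutant, bath_template, constraint_set(P_K = 1))
  pna <- fit1$perms[["P_Na"]]; pcl <- fit1$perms[["P_Cl"]]
  fit2 <- fit_ghk(noncap_wildtype, bath_template,
                  constraint_set(P_Na = pna, P_Cl = pcl))
  pk_wt <- fit2$perms[["P_K"]]

  fits <- list(mutant_baseline = fit1, wildtype_baseline = fit2)
  for (nm in names(other_conditions)) {
    tab <- other_conditions[[nm]]
    spec <- attr(tab, "condition")
    bath <- if (inherits(spec, "condition_spec"))
      condition_bath(spec, K_out = bath_template$K_out,
                     K_in = bath_template$K_in, Na_in = bath_template$Na_in,
                     Cl_in = bath_template$Cl_in,
                     temperature_C = bath_template$temperature_C)
    else bath_template
    cs <- if (stage3 == "all-free") {
      suppressWarnings(constraint_set())
    } else if (inherits(spec, "condition_spec") &&
               (spec$blocker == "amiloride" || spec$media == "low-Na")) {
      pk_base <- if (spec$genotype == "wild-type") pk_wt else 1
      constraint_set(P_K = pk_base, P_Cl = pcl)
    } else {
      constraint_set(P_Na = pna, P_Cl = pcl)
    }
    fits[[nm]] <- fit_ghk(tab, bath, cs, redistribute_cl = redistribute_cl)
  }
  structure(fits, class = c("ghk_staged", "list"))
}

#' @export
print.ghk_staged <- function(x, ...) {
  cat("Staged GHK fits (normalized to mutant baseline P_K = 1):\n")
  for (nm in names(x)) {
    p <- x[[nm]]$perms
    cat(sprintf("  %-28s P_K %6.3f  P_Na %6.3f  P_Cl %6.3f  SSE %8.3g\n",
                nm, p[["P_K"]], p[["P_Na"]], p[["P_Cl"]], x[[nm]]$sse))
  }
  invisible(x)
}

#' Chi-square comparison of two membrane-potential curves
#'
#' `X^2 = sum_k (Em_a(k) - Em_b(k))^2 / (sem_a(k)^2 + sem_b(k)^2)` over the
#' shared K+ grid, referred to the chi-square upper tail with one degree of
#' freedom per shared point.
#'
#' @param a,b [em_table()]s on identical K+ grids, with SEMs.
#' @return An `"htest"` with `statistic`, `parameter` (df) and `p.value`.
#' @export
compare_curves_chisq <- function(a, b) {
  stopifnot(inherits(a, "em_table"), inherits(b, "em_table"))
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$K_out, b$K_out)))
    stop("tables must share an identical K_out grid", call. = FALSE)
  if (!all(is.finite(a$Em_sem)) || !all(is.finite(b$Em_sem)))
    stop("both tables must carry SEMs", call. = FALSE)
  stat <- sum((a$Em_mean - b$Em_mean)^2 / (a$Em_sem^2 + b$Em_sem^2))
  dof <- nrow(a)
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = dof),
    p.value = stats::pchisq(stat, dof, lower.tail = FALSE),
    method = "Chi-square comparison of Em-vs-[K+]e curves",
    data.name = paste(condition_label(attr(a, "condition")), "vs",
                      condition_label(attr(b, "condition")))),
    class = "htest")
}

#' Nested-fit p-values for individual permeabilities
#'
#' For each nonzero permeability, the table is refitted with that
#' parameter fixed at zero (other free parameters refitted); the increase
#' in weighted SSE is referred to a chi-square distribution with 1 degree
#' of freedom, a likelihood-ratio-style test of whether the ion
#' contributes to the fit.
#'
#' @param fit a `"ghk_fit"`.
#' @return Named numeric vector of p-values (NA for parameters already 0).
#' @export
permeability_pvalues <- function(fit) {
  stopifnot(inherits(fit, "ghk_fit"))
  out <- stats::setNames(rep(NA_real_, 3), .PARAMS)
  for (par in .PARAMS) {
    if (fit$perms[[par]] <= 0) next
    v <- fit$constraints$values
    v[par] <- 0
    # keep originally-fixed parameters fixed; drop the tested one to zero
    args <- list(P_K = v[["P_K"]], P_Na = v[["P_Na"]], P_Cl = v[["P_Cl"]])
    if (sum(!is.na(unlist(args))) == 3L) {
      # all fixed after dropping: evaluate directly, nothing left to refit
      p0 <- .full_params(numeric(0),
                         list(values = unlist(args),
                              fixed = rep(TRUE, 3)))
      pred <- .model_em(p0, fit$table$K_out, fit$bath_template,
                        fit$redistribute_cl)
      sse0 <- sum(fit$weights * (fit$table$Em_mean - pred)^2)
    } else {
      cs0 <- do.call(constraint_set, args)
      sse0 <- fit_ghk(fit$table, fit$bath_template, cs0,
                      redistribute_cl = fit$redistribute_cl)$sse
    }
    out[par] <- stats::pchisq(max(sse0 - fit$sse, 0), df = 1,
                              lower.tail = FALSE)
  }
  out
}
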