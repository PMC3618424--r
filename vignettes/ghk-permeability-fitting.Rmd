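---
title: "Estimating relative ion permeabilities from membrane-potential data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative ion permeabilities from membrane-potential data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghkperm)
```

## The problem

Mammalian sperm travel through environments whose K⁺, Na⁺ and Cl⁻
concentrations differ several-fold, yet must hold a stable resting membrane
potential (Em) and then hyperpolarize at the right moment during
capacitation. The sperm-specific, pH-activated SLO3 K⁺ channel drives that
hyperpolarization; comparing wild-type against SLO3-knockout sperm across
conditions (capacitation state, external pH, channel blockers, ion
substitutions) lets one decompose the membrane's resting permeability into
relative K⁺, Na⁺ and Cl⁻ components.

The measurement itself is indirect: a potentiometric carbocyanine dye
(DiSC₃-(5)) reports Em in arbitrary fluorescence units, calibrated per
trace with valinomycin and stepped KCl additions; Em is then read at
several external K⁺ concentrations and the resulting Em-vs-[K⁺]ₑ curve is
fitted with the Goldman-Hodgkin-Katz (GHK) voltage equation to extract the
underlying permeabilities. `ghkperm` implements that entire chain —
forward models, calibration, constrained fitting, curve comparison — plus
a synthetic-data generator so the chain can be validated end to end
without access to a fluorimeter.

## Forward models

The single-ion Nernst potential is $E = \frac{RT}{zF}\ln(C_o/C_i)$ (inside
minus outside, mV). The three-ion GHK voltage is

$$
E_m = \frac{RT}{F}\,\ln
\frac{P_K [K^+]_o + P_{Na} [Na^+]_o + P_{Cl} [Cl^-]_i}
     {P_K [K^+]_i + P_{Na} [Na^+]_i + P_{Cl} [Cl^-]_o},
$$

with the anion's internal/external concentrations swapped as usual. Only
permeability *ratios* are identifiable from voltage data — the expression
is invariant under uniform rescaling of $(P_K, P_{Na}, P_{Cl})$ — so all
permeabilities here are expressed relative to the residual $P_K$ of
non-capacitated SLO3-mutant sperm at pH 7.4, assigned 1.0. $RT/F$ is
evaluated from CODATA constants at the bath temperature (26.73 mV at
37 °C); divalent ions are outside the model.

### Bath composition defaults

The default bath mirrors a HEPES-buffered saline: externally
Na⁺ = 151 mM (135 NaCl + 1 Na-pyruvate + 15 NaHCO₃), Cl⁻ = 143 mM, K⁺
variable. Internal concentrations are not directly measured by the
population assay, so the package adopts [K⁺]ᵢ = 120 mM (the value the
valinomycin calibration assumes) and configures [Na⁺]ᵢ = 14 mM,
[Cl⁻]ᵢ = 40 mM — chosen once so that the forward model with the
non-capacitated permeability presets reproduces the published resting
potentials (≈ −39 mV mutant, ≈ −45 mV wild-type at 5 mM K⁺):

```{r}
b <- bath_composition(K_out = 5)
ghk_voltage(perm_set(1.0, 0.13, 0.6), b)   # SLO3-mutant, non-capacitated
ghk_voltage(perm_set(1.6, 0.13, 0.6), b)   # wild-type, non-capacitated
```

All internal values are ordinary arguments and can be overridden per
bath. Nominal 0 mM substitutions (e.g. "1 mM Na⁺" media made with
impermeant cations) are floored at 10⁻³ mM so logarithms stay defined.

## Dye calibration

Valinomycin clamps the membrane at $E_K$, so each KCl addition moves the
plateau fluorescence to a known Nernst voltage. The calibration pairs the
post-step plateau fluorescence (median over a 30 s window ending just
before the next addition — the protocol reports steady state within
1–3 min but no detector, so a fixed window is the transparent choice)
with the theoretical anchor voltage, and converts fluorescence to mV by
piecewise-linear interpolation, extrapolating beyond the terminal anchors
with the terminal segment slopes (capacitated potentials can be more
negative than the most hyperpolarized anchor). A single least-squares
line mode is available for robustness comparisons; the default is
piecewise interpolation, and the mode used is recorded in the
calibration object.

One numerical subtlety: the customary anchor table
(−84.9, −75.0, −62.1, −46.9, −30.2 mV) is internally consistent with
*doubling* KCl aliquots added to the initial 5 mM — cumulative
concentrations 7.25, 11.75, 20.75 and 38.75 mM — rather than with the
one-decimal concentrations usually quoted alongside it (7.2, 11.7, 20.7,
38.7 mM), which reproduce two of the five voltages only to ≈0.2 mV at
37 °C. The package therefore uses the unrounded doubling-aliquot
concentrations as its default calibration steps:

```{r}
theoretical_calibration_voltages(c(5, 7.25, 11.75, 20.75, 38.75))
```

Because each trace carries its own calibration, the mapping absorbs any
gain/offset of the optical path: applying an affine transform to the
fluorescence channel leaves recovered voltages unchanged (a tested
invariant). For a quenching-mode cationic dye, fluorescence *falls* upon
hyperpolarization, i.e. $dF/dE_m > 0$; a calibration whose recovered
slope violates this is flagged (`dye_slope_ok = FALSE`) rather than
silently accepted.

## Staged constrained fitting

`fit_ghk()` minimizes the SEM-weighted residual sum of squares
$\sum_k w_k\,(E_m^{obs}(k) - E_m^{GHK}(k))^2$, $w_k = 1/\mathrm{sem}_k^2$
(unit weights when SEMs are absent), over the free permeabilities with a
box constraint at zero, using Levenberg-Marquardt (`minpack.lm::nls.lm`).
Because the objective can be shallow in $P_{Na}$, five starting points are
tried and the best optimum kept; the starts are deterministic log-spaced
values spanning [0.01, 20] rather than random draws, so a fit is a pure
function of its inputs. On three-point tables the optimizer agrees with
an exhaustive grid search (step 0.005) within one grid step — a tested
oracle.

`staged_fit()` encodes the identification strategy:

1. **Stage 1** — non-capacitated SLO3-mutant table, $P_K$ fixed at 1.0
   (the normalization reference), solving for $P_{Na}$ and $P_{Cl}$.
2. **Stage 2** — non-capacitated wild-type table with $P_{Na}, P_{Cl}$
   fixed at the stage-1 estimates, solving for $P_K$; the excess over 1.0
   is the SLO3 contribution at rest.
3. **Stage 3** — every other condition, with condition-appropriate
   constraints: capacitated, pH-8 and SLO3-blocker conditions hold
   $P_{Na}, P_{Cl}$ at stage 1 and free $P_K$ (the hypothesis under test
   is a $P_K$ change); amiloride and low-Na⁺ conditions fix $P_K$ at the
   genotype baseline and $P_{Cl}$ at stage 1 and free $P_{Na}$ (the
   blocker acts on the Na⁺ conductance). An `"all-free"` mode floats all
   three permeabilities for goodness-of-fit comparison; with no fixed
   parameter the scale is unidentifiable, which the constraint
   constructor warns about.

Per-permeability p-values are computed by a likelihood-ratio-style nested
comparison: refit with the permeability fixed at zero and refer the
increase in weighted SSE to $\chi^2_1$. This is an assumption of the
package (the figure-style p-values it emulates do not come with a stated
method) and is labelled as such.

Two further fitting variants expose the chloride physics:

* `fit_ghk_no_chloride()` fixes $P_{Cl} = 0$. On normal-chloride data its
  fit is visibly steeper and worse — chloride permeability "buffers" Em
  against external K⁺ changes, and the numerical $dE_m/d[K^+]_o$ at 5 mM
  is strictly smaller for the full model (a tested property).
* `redistribute_cl = TRUE` replaces the fixed internal Cl⁻ with its
  passive-redistribution value for every candidate parameter vector,
  for hyperpolarized conditions in which internal Cl⁻ cannot be assumed
  constant. Whether strong hyperpolarization is accommodated by a
  $P_{Cl}$ decrease or by Cl⁻ redistribution is deliberately left as two
  implemented modes, neither asserted as the truth.

## Passive chloride redistribution

Sperm lack active Cl⁻ pumping, so a sustained hyperpolarization drives
Cl⁻ out until $E_{Cl} = E_m$. At that fixed point Cl⁻ carries no net
flux and drops out of the GHK expression, giving the closed form
$E_m = \frac{RT}{F}\ln\frac{P_K K_o + P_{Na} Na_o}{P_K K_i + P_{Na} Na_i}$
and $[Cl^-]_i = [Cl^-]_o\,e^{E_m F / RT}$. `solve_passive_chloride()`
returns the pair plus the residual $|E_{Cl}([Cl^-]_i) - E_m|$ (zero to
machine precision, since the solution is analytic). Under capacitated
wild-type permeabilities ($P_K = 4.38$) it predicts internal Cl⁻ of
≈ 11 mM:

```{r}
solve_passive_chloride(perm_set(4.38, 0.13, 0.6), bath_composition(K_out = 5))
```

## The synthetic-data generator

`simulate_em_table()` draws, for each K⁺ on the default 5/10/20/30 mM
grid, `n = 11` Gaussian replicates of the condition's true GHK voltage
with `sigma = 2` mV and reports mean/SEM/n — the replicate count and the
few-mV SEM scale of the population assay it emulates. The ground-truth
permeabilities come from a YAML registry of condition presets (wild-type
non-capacitated 1.6/0.13/0.6; mutant 1.0/0.13/0.6; capacitated wild-type
4.38; pH-8 wild-type 8.2; pH-8 mutant 1.2 with the 0.15 → 0.12 Na⁺
pairing of that condition family; amiloride divides $P_{Na}$ by 6.5;
Ba²⁺/clofilium replace the wild-type $P_K$ by the mutant value). Two
registry entries are this package's own choices where only qualitative
statements exist: mutant capacitated $P_K = 1.1$ (a "slight increase")
and wild-type capacitated $P_K = 2.4$ at pH 7 (reproducing the ≈6 mV
pH-7 hyperpolarization); both are marked `chosen: true` in the registry.
The two $P_{Na}$ conventions (0.13 elsewhere, 0.15 → 0.12 in the pH-8
family) are kept side by side rather than reconciled.

In low-Cl⁻ media the generator replaces internal Cl⁻ by its passive
fixed-point value, reproducing the experimentally observed steepening of
the Em-vs-K⁺ relation and making the chloride-free fit adequate there.
Mixed populations (e.g. partially capacitated samples) are modelled as a
population-weighted mean *in voltage space* — measured population values
correspond to the average of subpopulations — with the dye-signal-space
alternative out of scope. `simulate_fluorescence_trace()` maps voltages
to arbitrary units through an affine dye model with positive gain
(default 5 AU/mV, offset 600 AU, noise 5 AU) and appends the
valinomycin/KCl calibration tail, so calibration round-trips can be
tested at zero noise (exact) and at realistic noise (≤1 mV).

What the generator does *not* emulate: dye equilibration kinetics,
mitochondrial dye partitioning, photobleaching, per-cell channel
stochasticity, or any coupling between conditions beyond the preset
registry. Passing tests therefore validate the analysis chain under the
model's own assumptions, not the biology of real traces.

## What recovery simulations can and cannot show

With the default design (four K⁺ points, σ = 2 mV, n = 11) the
linearized standard error of the stage-1 estimates is ≈0.0045 for
$P_{Na}$ but ≈0.106 for $P_{Cl}$: the design carries limited information
about chloride, and no estimator can beat that floor. The test suite
accordingly checks that recovered $P_{Na}$ and $P_K$ have median absolute
errors below 10% of truth, and that the $P_{Cl}$ error sits at its
information floor (within 1.3× of the linearized bound) with bias below
5% for all three. Equivalently: a single staged fit pins the K⁺/Na⁺ side
tightly, while $P_{Cl}$ from one experiment of this size is a
factor-of-±0.1-to-0.15 quantity.

Problem sizes used throughout the suite — 200 recovery replicates, the
eight-condition pipeline at n = 11, a 30,000-point grid-search oracle on
three-point tables — were chosen as the smallest sizes at which the
statistical checks are stable.

## Numerical choices

* Concentrations floored at 10⁻³ mM; temperature restricted to [0, 50] °C.
* Weighted SSE with $1/\mathrm{sem}^2$ weights whenever SEMs are present.
* Optimizer: `nls.lm`, `maxiter = 200`, `ftol = ptol = 10⁻¹²`, lower
  bounds 0, five log-spaced deterministic starts in [0.01, 20].
* Fixed constraint values are returned bit-identical, never re-estimated.
* The chloride fixed point is analytic; its residual is reported anyway
  as a numerical invariant (< 10⁻⁶ mV).
* All generator randomness flows through a locally-scoped RNG seeded
  from `generator_config(seed=)`; the global RNG stream is untouched,
  and the pipeline derives per-condition seeds as `seed + 1000·i`.

## Limitations

* Monovalent three-ion GHK only; no divalent extension, no constant-field
  current equations, no time-dependent membrane dynamics.
* The calibration assumes KCl additions change K⁺ only; the accompanying
  ≤34 mM Cl⁻ increase is ignored because anchors are K⁺-Nernst by
  construction.
* Nested-fit p-values assume the weighted SSE difference is $\chi^2_1$
  under the null — adequate for screening, not a substitute for a full
  error analysis.
* Permeabilities are relative; nothing here determines absolute
  conductances.
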