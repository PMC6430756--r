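---
title: "A mechanistic isotherm for PEG-induced protein precipitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic isotherm for PEG-induced protein precipitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegprecip)
```

## The model

Adding polyethylene glycol (PEG) to a protein solution drives a phase
transition: above a protein- and PEG-dependent threshold, protein leaves
solution as an amorphous precipitate. The classical description is the
Cohn equation, `log(S) = s0 - alpha * m`, a purely empirical straight line
in semi-log coordinates that treats the initial protein concentration as
fixed. `pegprecip` implements a mechanistic alternative that borrows its
picture from hydrophobic interaction chromatography: the driving force of
precipitation is the reorganization of well-ordered water on the hydrophobic
patches of the protein surface into bulk-like water when protein–protein
contacts form.

The stoichiometric picture is an equilibrium in which one PEG molecule
affects `n` protein molecules `P`, producing precipitate `Pp` stabilized by
`beta` bulk-like ordered water molecules per protein:

    n P + PEG  <=>  Pp + n*beta W_B

Writing the mass-action law for this equilibrium, assuming constant
activity coefficients, and absorbing the water-activity term (linear in the
precipitated concentration) into the equilibrium coefficient gives the
implicit isotherm solved by this package:

    q^(1 + n*beta) = k_eq * c_p^n * c_peg

with

* `q` — precipitated protein concentration (mol/L),
* `c_p` — supernatant protein concentration (mol/L),
* `c_peg` — PEG concentration (mol/L),
* `k_eq` — lumped equilibrium coefficient (stored and fitted as `ln_k_eq`),
* `n` — proteins affected per PEG molecule (positive, not necessarily an
  integer),

and a hydration number that itself depends on composition,

    beta = beta0 * exp(beta1 * c_peg + beta2 * c_p0),

where `c_p0` is the *initial* protein concentration, `beta0` is the
hydration number at infinite dilution, and `beta1`, `beta2` (L/mol) scale
its PEG and protein dependence. The exponential form mirrors established
hydration-number models for salt ions.

Two closures complete the computable model. First, mass balance: the model
equations never state it, but supernatant-depletion measurement implies
`q + c_p = c_p0`, which we adopt, making the isotherm a single implicit
equation in `q` on `[0, c_p0]`. Second, units: all concentrations are
molar internally, because `beta1` and `beta2` carry L/mol and prediction
errors are reported in mol/L. The unit convention inside `k_eq` is not
derivable from published parameter magnitudes alone; the molar convention
is used consistently, and all recovery results are internally consistent
under it.

## Solving the equilibrium

For `c_peg, c_p0 > 0` the residual
`f(q) = q^(1+n*beta) - k_eq (c_p0-q)^n c_peg` is negative at `q = 0`,
positive at `q = c_p0`, and strictly increasing in between whenever all
concentrations are below 1 mol/L (protein solutions sit orders of magnitude
below this), so the equilibrium root is unique. `solve_equilibrium()`
brackets it on `[0, c_p0]` and applies Brent's method to the log-form
residual

    g(q) = (1 + n*beta) ln q - (ln_k_eq + n ln(c_p0 - q) + ln c_peg),

which has the same sign structure but cannot overflow. Numerical choices
that matter:

* **Extreme phase splits.** When the root lies within a relative `1e-6` of
  either endpoint (almost no precipitation, or almost none left in
  solution), the solve is repeated in a log-substituted coordinate
  (`log q`, or `log c_p`) so the answer keeps full *relative* precision;
  roots beyond the double-precision range of the bracket collapse to the
  exact endpoint. Against a 200-iteration sign-bisection oracle the solver
  agrees to better than `1e-10` relative across randomized realistic
  instances (the acceptance script recomputes this).
* **Degenerate wells.** `c_peg = 0` or `c_p0 = 0` short-circuit to `q = 0`;
  no solver call, no tolerance question.
* **Fitting fast path.** Parameter estimation evaluates thousands of
  solves; it uses a vectorized fixed-count bisection (90 halvings) of the
  same log-form residual, accurate to `c_p0 * 2^-90` absolute, which is far
  below measurement scale. The public solver and the fast path are
  cross-checked in the test suite.

## The screen the generator emulates

The synthetic screen reproduces a high-throughput 96-well design: eight
equidistant initial protein levels from 1.5 to 12 mg/mL; twelve equidistant
PEG levels up to a protein-class maximum (0.056 mol/L for small proteins;
0.02 mol/L for mAb-like proteins, which precipitate at lower PEG);
triplicates; randomized well positions on sequentially filled plates. The
phrase "twelve equidistant steps" is concretized as
`seq(peg_max/12, peg_max, by = peg_max/12)` — nonzero, equidistant levels
reaching the maximum.

Measurement error is multiplicative lognormal (UV-280 after dilution scales
with signal), mean-corrected so the expected reading equals the true
supernatant concentration, with a default CV of 2 %. A configurable
fraction of replicates (default 2 %) is replaced by gross errors —
multiplied or divided by a factor drawn from 1.5–3 — standing in for
pipetting and carry-over mistakes. These noise magnitudes are package
defaults chosen as realistic for robotic screens, not published values, and
are exposed in the config.

What the generator does **not** emulate: buffer chemistry and pH-dependent
parameter drift (each parameter set is valid for one protein at one pH),
incubation kinetics (equilibrium is assumed; PEG precipitation is fast),
non-equilibrium artifacts such as gel formation, and instrument-specific
calibration error. Passing recovery tests on simulated screens therefore
demonstrates the *estimator* works when the model is true; it cannot
demonstrate the model is true for a new protein — that requires held-out
experimental data.

## Pretreatment and the calibration/validation split

Each replicate set is screened before averaging: if the percentage standard
error (SEM as a percent of the mean) exceeds 5 %, the replicate farthest
from the median is dropped and the criterion re-evaluated, never going
below two retained values; a still-violating pair is flagged rather than
truncated further. Reading the 5 % rule as SEM-based is the literal
interpretation of "percentage standard error"; a relative-SD variant is
available (`measure = "sd"`). The farthest-from-median elimination order is
this package's concretization — the elimination mechanics are not otherwise
specified.

The split rule removes the three highest protein levels and the two highest
PEG levels from calibration; they form the validation set. On the full
8 × 12 grid this yields 50 calibration and 46 validation conditions, and
validation deliberately lies *outside* the calibration range, so the
reported RMSEP measures extrapolation, not interpolation.

## Parameter estimation

The loss is the sum of squared errors on replicate-mean supernatant
concentrations in mol/L — the quantity UV-280 actually measures after
centrifugation. (The original workflow's loss is unstated; this is a
documented package decision.) Optimization runs over
`(ln_k_eq, n, ln beta0, beta1, beta2)` — the log scales condition a search
space spanning many orders of magnitude — inside default bounds
`ln_k_eq ∈ [0, 60]`, `n ∈ [0.5, 10]`, `ln beta0 ∈ [-12, 0]`,
`beta1 ∈ [0, 10^3]`, `beta2 ∈ [0, 10^5]` L/mol.

Each of `restarts` (default 10) seeded Latin-hypercube starts — `beta1` and
`beta2` drawn with a cubic bias toward small magnitudes, where plausible
values live — is refined by bounded simulated annealing with a reflecting
Gaussian proposal, then polished by bounded Levenberg–Marquardt on the
residual vector. The best polished solution wins; ties go to the first.
The whole procedure is bit-reproducible given `(seed, restarts, bounds,
data)`. On noiseless screens generated from each bundled reference
parameter set, every parameter is recovered to machine precision
(calibration RMSE below `1e-19` mol/L); with 2 % CV triplicate noise the
recovered `n` typically lands within ~5–13 % of truth across noise
realizations — the residual uncertainty is sampling variance of the
estimator, not optimizer failure (doubling the restarts changes nothing).

Identifiability guards: fitting refuses designs with fewer than five
distinct conditions or without at least two distinct levels in both
concentration axes, where the five parameters are structurally confounded.

## Problem sizes and runtime

The shipped tests and the acceptance script run the full workflow at the
study's own scale — 96-condition screens, 10 restarts, 1000-instance solver
randomization — which completes in a few minutes on a single core; the
vectorized bisection fast path is what keeps a full five-protein recovery
sweep cheap.

## Known limitations

* One parameter set per protein and pH; no pH- or PEG-size dependence is
  modeled (both are flagged as open research directions).
* PEG only — no salt (Hofmeister) precipitation, no multi-component feeds.
* No uncertainty quantification on fitted parameters (no profile
  likelihood or bootstrap); the diagnostics table records per-restart
  objectives only.
* The % w/w → mol/L PEG conversion assumes a configurable solution density
  (default 1.0 g/mL, dilute-aqueous); published screens rarely state their
  convention.
* BSA and mAb molecular weights in the registry (66.5 and 150 kDa) are
  editable textbook defaults, not measured values.
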