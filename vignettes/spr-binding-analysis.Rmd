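---
title: "Models and methods behind sprbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sprbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprbind)
```

`sprbind` analyses label-free small-molecule binding screens measured by
surface plasmon resonance (SPR). This vignette documents the models the
package implements, the defaults and tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.
The running reference case is a screen of cannabinoids against the
immobilized ectodomain of the P2X4 receptor, an ATP-gated ion channel,
with the antagonists BX430 and 5-BDBD as probe compounds.

## The 1:1 Langmuir interaction model

A sensorgram records response units (RU, proportional to bound mass at
the sensor surface) against time. For a pseudo-first-order 1:1
interaction between flowed analyte at constant concentration $C$ and an
immobilized ligand with capacity $R_{max}$,

$$\frac{dR}{dt} = k_{on} C (R_{max} - R) - k_{off} R,$$

with analytic association-phase solution

$$R(t) = R_{eq}\left(1 - e^{-(k_{on}C + k_{off})t}\right), \qquad
R_{eq} = \frac{C\,R_{max}}{C + K_D}, \qquad K_D = \frac{k_{off}}{k_{on}},$$

and exponential dissociation $R_0 e^{-k_{off}t}$ after the injection
ends. `association_response()`, `dissociation_response()` and
`steady_state_response()` implement these closed forms; the test suite
verifies them against adaptive numerical integration of the ODE
(`deSolve`, tolerances $10^{-12}$) to better than $10^{-6}$ RU across a
log-grid of rate parameters. The model deliberately excludes
mass-transport limitation, surface heterogeneity and higher-order binding
stoichiometries: compounds that violate it should be caught by the QC
flags, not absorbed by extra parameters.

## Preprocessing: double referencing and solvent correction

Raw traces carry bulk refractive-index shifts, baseline drift and
systematic per-cycle disturbances. `preprocess_cycles()` applies, in
order:

1. **Reference subtraction** — the matched reference flow-cell trace is
   subtracted pointwise (identical time grids are required, never
   interpolated).
2. **Solvent correction** (optional) — DMSO-only calibration cycles
   spanning the assay's DMSO design range (eight points, 2.5–3.8 %) give
   pairs (reference plateau, active − reference plateau); a quadratic
   polynomial fitted to these pairs is evaluated at each sample cycle's
   reference bulk response and subtracted. Correction sets acquired
   before and after a block of sample cycles are interpolated linearly in
   cycle index — the simplest defensible model of drift between
   calibrations. Evaluation outside the calibrated range is flagged, not
   refused.
3. **Blank subtraction** — the mean of the zero-concentration blank
   cycles (processed identically) is subtracted.

The order — reference, then solvent, then blank — is the standard
double-referencing convention; the pipeline treats it as fixed. Plateau
reads everywhere use the median of the final 20 % of the association
window (`plateau_fraction = 0.2`), which is robust to single-point noise.
On noise-free synthetic data with known drift and bulk artifacts the full
chain returns the ideal binding curve to within $10^{-9}$ RU (a test
asserts this).

## Global kinetic fitting

`fit_kinetics()` fits one $(k_{on}, k_{off}, R_{max})$ triple jointly to
all non-zero concentration cycles of an analyte, minimizing the summed
squared residual over association and dissociation windows with
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`).

Key choices:

- **Log-parameter space.** Rates span orders of magnitude; optimizing
  $\log k_{on}, \log k_{off}, \log R_{max}$ keeps them positive and well
  conditioned. Bounds: $k_{on} \in [10^2, 10^9]$ 1/(M·s),
  $k_{off} \in [10^{-5}, 1]$ 1/s, $R_{max}$ at most 10× the theoretical
  (or, failing that, observed) capacity. A solution pinned at a bound is
  flagged `at_bound`.
- **Deterministic initialization.** $k_{off}$ from a log-linear
  regression of the dissociation tail at the highest concentration;
  $K_D$ and $R_{max}$ from a steady-state prefit of plateau responses;
  $k_{on} = k_{off}/K_D$. No random restarts, so identical inputs give
  identical fits.
- **Convergence** at relative SSR change $10^{-10}$
  (`ftol = ptol = 1e-10`, 200 iterations).
- **Standard errors** from the Jacobian at the optimum on the log scale,
  mapped back by the delta method; the derived $K_D$ standard error uses
  the independent-rates delta approximation.

Noise-free synthetic concentration series are recovered to relative error
below $10^{-6}$; on the screening design with 0.5 RU noise the median
relative error of both rates over 20 seeds is well under the 5 %
validation threshold (typically ≈ 0.3 %).

### Detection and QC flags

The published screen reports non-binders as "n.d." rather than omitting
them, and `sprbind` follows that practice. A compound is
`not_detectable` when no cycle's plateau read exceeds
`noise_multiplier` (default 3) times the baseline noise sd — plateau
reads rather than pointwise maxima, so a single noise excursion cannot
promote a non-binder — or when fewer than two distinct concentrations
are usable. `matrix_binding` fires when the observed response exceeds
the theoretical capacity
$R_{max}^{theo} = (MW_{analyte}/MW_{ligand})\cdot R_{immobilized}$,
the signature of analyte partitioning into the dextran matrix.
`slow_dissociation` fires when a cycle retains more than 50 % of its
peak at the end of the dissociation window (default
`slow_dissociation_retention = 0.5`; e.g. $k_{off} = 10^{-4}$ 1/s over
420 s retains $e^{-0.042} \approx 96\,\%$). For the reference case, an
immobilization level of 16,000–18,000 RU and cannabinoid analytes of
286–330 g/mol are consistent with the reported 158–205 RU capacity span
for a ligand molecular weight near 29 kDa — the size of the receptor
ectodomain construct — but because the construct's exact mass is not
published, `theoretical_rmax()` takes the ligand MW as an explicit
input.

## The competition model

For two analytes competing for a single site at equilibrium, the
occupied fractions are

$$FO_A = \frac{1}{1 + \frac{K_{DA}}{C_A}\left(1 + \frac{C_B}{K_{DB}}\right)},$$

symmetrically for B. This is the steady state of the shared-site kinetic
scheme
$\dot\theta_A = k_{on,A} C_A (1 - \theta_A - \theta_B) - k_{off,A}\theta_A$
(and symmetrically), which `simulate_competition_odes()` integrates as
the independent oracle: the closed form and the ODE steady state agree to
$<10^{-9}$ across a log-grid of parameters. Two conventions are
documented and tested: $FO = 0$ at $C = 0$ (the formula is singular
there, and the limit recovers the single-ligand isotherm), and mixture
concentrations $C_A, C_B$ are the **per-component** final concentrations
in the injected mixture (1 μM each for the probe-pair experiment, where
the dilution description is ambiguous between 1 μM each and 0.5 μM
each).

The predicted combined response under competition is
$FO_A R_{max,A} + FO_B R_{max,B}$; under independent binding it is the
exact sum $RU_A + RU_B$ of the single-analyte experimental responses.
$R_{max}$ values for the competitive prediction are always explicit
inputs (fitted or theoretical), never inferred silently — the
published study's own values are not recoverable from its printed
numbers, which is why `classify_competition()` also accepts an externally
supplied `theoretical_competitive` column.

### The classifier

`classify_competition()` assigns the label of the nearer theoretical
value, guarded by a relative margin $m$ (default 0.1): competitive when
$|RU_{AB} - RU^{comp}| < |RU_{AB} - RU^{noncomp}|(1 - m)$, symmetrically
for non-competitive, otherwise inconclusive. The published study states
only that the observed value "closely resembled" one prediction; the
margin formalizes that rule, reproduces all three fully quantified
published verdicts (BX430 + 5-BDBD non-competitive; CBD and CBV
competitive with 5-BDBD), and returns `inconclusive` on exact ties. On
simulated experiments at assay-like scale (probe kinetics, 1 μM each,
0.5 RU noise) the classifier recovers the true mechanism in ≥ 95 % of
200 replicates (typically ≈ 100 %).

## The synthetic-data generator

No public instrument data exist for the reference screen, so the
generator emulates the assay design as the package's study conditions:

- concentration series: 3-fold dilutions 0.4, 1.2, 3.6, 10.8, 32.4,
  97.2, 300 μM — the broad range used when analyte affinity is unknown.
  (A 3-fold ladder between 0.4 and 300 μM has exactly seven points.)
- phases: 30 s baseline, 180 s association, 420 s dissociation at 1 Hz.
  Sample-cycle contact times are not published; these are conventional
  values for small-molecule kinetics at these rates.
- noise: i.i.d. Gaussian, sd 0.5 RU per time point — a typical
  short-noise figure for this instrument class.
- artifacts: optional linear drift (RU/s) and a bulk refractive-index
  jump during the injection, both common to the two flow cells, so
  double referencing removes them exactly.
- panels: binder $K_D$ log-uniform in $[10^{-6}, 3.4\times10^{-4}]$ M
  (the affinity envelope of the reference screen), $k_{off}$ log-uniform
  in $[0.05, 0.5]$ 1/s, binder $R_{max}$ 100 RU; non-binders produce
  artifact-plus-noise traces only.
- competition: report values are equilibrium reads; the non-competitive
  mechanism is independent sites (the additive null made generative), the
  competitive mechanism is the shared-site ODE integrated to steady
  state.

Determinism: every generator accepts a `seed`, restores the session RNG
afterwards, and produces bit-identical output for identical (seed,
arguments).

The generator does **not** emulate mass-transport limitation, rebinding,
surface decay or regeneration scarring, analyte depletion, non-Gaussian
noise bursts, or carry-over between cycles. Passing recovery tests
therefore certify the estimator and classifier under the stated model
assumptions — not robustness to every artifact of real instrument data.

## Numerical choices and degenerate inputs

- ODE oracles use `deSolve::ode` (lsoda) with `rtol = 1e-10`,
  `atol = 1e-12`; the competition system is linear in the occupancies, so
  the default integration horizon is 40 divided by the magnitude of the
  slowest eigenvalue of its rate matrix, which guarantees relaxation to
  steady state at the $10^{-9}$ comparison tolerance.
- Readers refuse, rather than repair, invalid inputs: non-monotone time,
  non-finite responses, unknown phases, or inconsistent per-cycle
  concentrations raise errors naming the offending cycle. Writers emit
  numerics at 12 significant digits (`%.12g`), making write–read a
  practical identity.
- A flat or sub-noise cycle set yields a `not_detectable` result object,
  not an exception; a compound-level failure inside `run_screen()`
  degrades to an n.d. row with its reason recorded.
- Screen report TSVs print rates in 4-significant-digit scientific
  notation (e.g. `1.099E+5`) and the literal `n.d.` for non-detectable
  compounds, matching published table style.

## Validation problem sizes

The package's validation studies use: 20 seeded replicates for kinetic
parameter recovery on the full screening design; 200 seeded replicates
for classifier mechanism recovery; a 28-compound simulated panel with 13
true binders for the end-to-end screen; and $6\times$–$16\times$
log-grids for the oracle comparisons. These sizes give stable medians
and proportions while keeping the whole suite fast enough to run on
every change.

## Known limitations

- Only the 1:1 model is implemented; two-state, bivalent and
  heterogeneous-ligand schemes are out of scope, as is kinetic
  (time-resolved) competition fitting and any ternary/allosteric
  coupling model.
- The competition statistic is an equilibrium argument; it assumes the
  combined injection reaches (near) steady state at the report point.
- Standard errors are asymptotic (Jacobian-based) and ignore residual
  autocorrelation, which real sensorgrams exhibit.
- The classifier's margin trades decisiveness against a third
  `inconclusive` outcome; with the default 0.1 it reproduces the
  published calls, but pairs whose two predictions are close together
  are intrinsically hard to classify at realistic noise.
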