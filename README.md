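# sprbind

Surface plasmon resonance (SPR) binding screens and competitive-binding
analysis for small-molecule panels, with the P2X4 receptor cannabinoid
screen as the worked reference case.

SPR measures mass accumulation at a sensor surface in real time: a
receptor ("ligand", in SPR convention) is immobilized on a chip, a
compound ("analyte") flows over it, and the instrument reports a
sensorgram — response units (RU) versus time across an association phase
(analyte flowing) and a dissociation phase (buffer only). `sprbind` turns
raw Biacore-style traces into binding parameters and binding-site
assignments:

- **Preprocessing** — double referencing (reference flow-cell and
  zero-concentration blank subtraction) and DMSO solvent correction from
  eight-point calibration cycles.
- **Kinetics** — global 1:1 Langmuir fitting across a concentration
  series. The model is `dR/dt = kon·C·(Rmax − R) − koff·R`, whose
  association-phase solution is `R(t) = Req·(1 − e^−(kon·C+koff)·t)` with
  `Req = C·Rmax/(C + K_D)` and `K_D = koff/kon`; dissociation decays as
  `R0·e^−koff·t`. Fits return kon, koff, K_D, Rmax with standard errors
  and QC flags (`not_detectable`, `matrix_binding`, `slow_dissociation`,
  `at_bound`).
- **Competition** — for two analytes A and B sharing one site at
  equilibrium, the fractional occupancies are

  ```
  FO_A = 1 / (1 + (K_DA/C_A)(1 + C_B/K_DB))      (symmetric for B)
  ```

  The predicted combined response under competition is
  `FO_A·Rmax_A + FO_B·Rmax_B`; under independent binding it is the sum
  `RU_A + RU_B` of the single-analyte responses. A nearest-value rule with
  a relative margin classifies each pair as competitive, non-competitive
  or inconclusive.
- **Simulation** — a generator for noisy sensorgram cycle sets, DMSO
  calibration cycles, screening panels with known binder status, and
  competition experiments under true competitive (shared-site ODE) and
  non-competitive (independent-sites) mechanisms, used throughout the test
  suite for parameter- and mechanism-recovery studies.
- A small thermodynamic utility converts docking free energies to
  inhibition constants, `Ki = exp(ΔG/RT)`.

Everything is tibble-in, tibble-out: sensorgrams are long tables with
columns `cycle_id, flow_cell, analyte_id, concentration_M, phase, time_s,
response_RU`, and fitted objects support `tidy()`, `glance()`,
`augment()` and `autoplot()`.

## Worked example

Simulate a CBD-like analyte (kon ≈ 1.9·10⁴ 1/(M·s), koff ≈ 0.02 1/s,
i.e. K_D ≈ 1 μM) on the 3-fold 0.4–300 μM screening series, preprocess
and fit:

```r
library(sprbind)

cs  <- simulate_cycle_set("CBD-like", k_on = 1.9e4, k_off = 0.02,
                          R_max = 180, noise_sd = 0.5, seed = 42)
fit <- fit_kinetics(preprocess_cycles(cs))
fit
#> <spr_kinetic_fit> analyte CBD-like (7 cycles)
#>   k_on  = 1.903e+04 1/(M s)
#>   k_off = 0.02002 1/s
#>   K_D   = 1.052e-06 M
#>   R_max = 180 RU
```

With 0.5 RU of noise the fitted rates land well within 1% of the
simulation truth. Classify the published P2X4 competition measurements
(single and combined responses of each cannabinoid with the antagonist
probe 5-BDBD, plus the reported competitive predictions):

```r
classify_competition(p2x4_competition())
#>   analyte_a analyte_b RU_ab theo_competitive theo_noncompetitive  label
#> 1 BX430     5-BDBD     39.3             17.2                57.4  non_competitive
#> 2 CBD       5-BDBD      6.9              6.7                12.7  competitive
#> 3 CBV       5-BDBD      2.1              4.37                7.3  competitive
```

The combined BX430 + 5-BDBD response sits near the additive sum, so the
two probes occupy distinct sites; CBD and CBV sit near the shared-site
prediction, identifying them as competitive binders of the 5-BDBD site.
And the docking-energy conversion:

```r
inhibition_constant_from_energy(-7.14) * 1e6   # ΔG in kcal/mol -> Ki in uM
#> 5.84
```

A thin command-line wrapper lives at `inst/cli/sprbind`
(`simulate | screen | compete` subcommands over the same functions).

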