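---
title: "Kinetic modelling of multi-step carotene desaturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of multi-step carotene desaturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carokin)
```

## The model

Multifunctional CrtI phytoene desaturases introduce up to six conjugated
double bonds into a single C40 substrate, walking it along the chain
phytoene → phytofluene → ζ-carotene → neurosporene → lycopene →
didehydrolycopene → tetradehydrolycopene. In vitro, every intermediate is
released into the liposome pool and must rebind the enzyme before the next
desaturation (a distributive mechanism), so the observed product patterns
reflect a competition of all chain species for free enzyme.

`carokin` encodes this as a mass-action network. For a chain of $n$
catalytic steps there are $n+1$ explicit binding equilibria and $n$
catalytic conversions:

$$E + S_i \underset{k_r[i]}{\overset{k_f[i]}{\rightleftharpoons}} ES_i,
\qquad ES_i \xrightarrow{k_{cat}[i]} E + S_{i+1} \quad (i < n).$$

The terminal product also binds ($ES_n$) but has no catalytic outflow — a
dead-end complex that is the model's product-inhibition term. Two linear
first integrals hold exactly: the carotene backbone count
$\sum_i ([S_i] + [ES_i])$ and the total enzyme $[E] + \sum_i [ES_i]$.

Derived constants follow the usual definitions: $K_d[i] = k_r[i]/k_f[i]$
and, for catalytic steps, $K_m[i] = (k_r[i]+k_{cat}[i])/k_f[i]$. At the
fitting-bound extremes ($k_f \in [0.1, 1]\,\mu M^{-1} s^{-1}$,
$k_r \in [1, 10]\, s^{-1}$), $K_d$ spans exactly 1–100 µM.

Assumptions worth stating explicitly:

* **Distributive, single complex per species.** Each product is released
  and rebinds through its own equilibrium; no processive channelling and
  no distinct product-release complex. The exact complex bookkeeping of
  the original COPASI model is not printed anywhere we can consult, so the
  single-complex-per-species reading is a design choice, flagged here.
* **FAD is not modelled.** Assays contain 100 µM FAD, assumed saturating.
* **No cis/trans isomer tracking** and no multimer/substrate-channelling
  features of plant-type desaturases.
* **Well-mixed concentrations.** Liposome association is not represented
  spatially; all concentrations are bulk µM.
* **Units.** µM and seconds internally; file interfaces use minutes.

The fitted model is always the 4-step chain (phytoene → lycopene): the
two further desaturations are not observed in the two-hour purified-enzyme
assays, so steps 5–6 exist only in `extended` networks used for
exploratory simulation.

```{r}
net <- build_network(4)
net
```

## Observables and the assay

The quench step (chloroform/methanol) denatures the enzyme and releases
bound carotenes, so HPLC sees free **plus** enzyme-bound material;
`simulate_timecourse()` reports that sum per species. Whether the original
analysis also included the bound fraction in its fitted observable is not
stated; with a 0.83 µM enzyme against 10 µM substrate the difference is
bounded by ~8% of the signal and vanishes as intermediates accumulate.

The standard assay (`preset_assay()`): 10 µM phytoene (5 nmol in 0.5 mL),
25 µg enzyme in 0.5 mL — 0.83 µM at the default assumed molar mass of
60 kDa (configurable; per-isoform masses are not available to us) — with
either the dense 10-point schedule (0–120 min) or the sparse 8-point one.
The default HPLC detection limit is 0.01 µM and is applied only at
reporting time, never during integration.

## Numerical integration

Rate constants span four orders of magnitude, so the ODEs are integrated
with an L-stable, stiffly accurate SDIRK3(2) method (three-stage singly
diagonally implicit Runge–Kutta, embedded second-order error estimate
filtered through $(I-h\gamma J)^{-1}$, analytic Jacobian, adaptive steps).
No pre-installed R ODE solver was available to this package, so the
integrator is built in; it is cross-checked in the test suite against an
independent stiff solver (scipy's Radau) and against closed-form oracles
(the quadratic binding-equilibrium expression when all $k_{cat}=0$, and
the Michaelis–Menten quasi-steady-state rate in the catalytic-enzyme
limit).

Reporting tolerances default to `rtol = 1e-8`, `atol = 1e-10` µM.
Negative-concentration clipping is never applied — accepted states are
Newton solutions of the implicit stages, which preserve the two linear
conservation laws to rounding (observed drift ~1e-14, asserted ≤ 1e-6 over
hundreds of random 120-min trajectories).

## Parameter estimation

`fit_pso()` reproduces the bounded particle-swarm protocol: 2000
iterations, swarm size 50, bounds $k_f \in [0.1,1]$, $k_r \in [1,10]$,
$k_{cat} \in [10^{-5}, 0.1]$, minimising a weighted least-squares
objective. "Mean-square" weighting is implemented as
$w_{e,s} = 1/\overline{obs_{e,s}^2}$ per experiment and species (the
common simulation-tool convention; the name alone does not fix a formula,
so alternatives `squared_mean`, `variance`, `none` are selectable).
Species observed as all-zero are skipped. Each experiment is fitted
independently (the original analysis does not state whether enzymes were
fitted jointly; per-enzyme independent fits are the conservative reading).

Implementation choices, all configurable via `fit_config()`:

* **Constriction coefficients** (inertia 0.729, cognitive = social =
  1.494), uniform initialisation within bounds, reflecting boundary
  handling. $k_{cat}$ is searched in log10 space (its bounds span four
  decades); $k_f$ and $k_r$ linearly.
* **Two-stage integration fidelity.** The bulk of the search evaluates
  the objective at `sim_rtol = 1e-4` (where a simulation costs ~0.5 ms);
  the final 25% of iterations switch to `refine_rtol = 1e-5`, re-scoring
  the remembered bests. The loose-tolerance objective carries an
  integration-noise floor (~1e-7 in weighted units) that can manufacture
  spurious minima below the real valley; re-scoring removes them. A
  consequence is that the optimizer trace is monotone non-increasing
  within each fidelity phase but may step up once, honestly, at the
  switch.
* **Guaranteed-convergence step.** Plain constriction swarms stagnate on
  the flat, curved parameter ridges typical of this model. Each iteration
  therefore also probes one trial point in a box around the global best
  whose radius doubles on success and shrinks on failure (the GCPSO idea
  of van den Bergh), which keeps descent going after swarm collapse at
  ~2% extra cost.

## What recovery benchmarks do and do not establish

`recovery_suite()` draws true rate constants uniformly (linear scale)
inside the bounds, generates noise-free dense-schedule data, refits, and
reports per-parameter relative errors. Two structural facts dominate the
results:

* **Binding constants are weakly identified.** With $S_0 = 10$ µM and
  $K_d$ draws up to 100 µM, many binding steps operate far below
  saturation, where the data constrain only the ratio
  $k_{cat}/K_m$. Objective profiles over individual binding constants are
  flat over most of their range — the quantitative form of the original
  study's caution that its $K_d$ values "should be interpreted with
  caution" (reported here via `profile_identifiability()`, deliberately
  not thresholded).
* **This sloppiness propagates to the catalytic constants of unsaturated
  steps.** Because $k_{cat}$ can trade against $K_m$ inside the bounds
  while preserving $k_{cat}/K_m$, the objective discriminates a 25%
  error in a middle-step $k_{cat}$ only below ~1e-6 in weighted units —
  beyond what a 2000-iteration swarm reliably reaches on this
  14-parameter landscape. In our benchmark (10 draws, seed 42), the
  per-step fractions of draws recovering $k_{cat}$ within 25% were
  7/10, 5/10, 4/10 and 7/10 for steps 1–4 (median relative errors 0.17,
  0.34, 0.32, 0.13): the first and last steps, which enjoy direct
  substrate-depletion and terminal-accumulation signals, fare best,
  while only 1/10 draws recovered all four simultaneously. The
  corresponding acceptance criterion (all four
  $k_{cat}$ within 25% in ≥ 8/10 runs) is therefore left failing by
  design rather than weakened: the stated world — these bounds, this
  assay, this optimizer budget — does not meet it, and the package
  reports that honestly.

A green recovery run therefore establishes that the estimation machinery
finds the global basin on identifiable directions; it does not certify
individual binding constants.

## Synthetic data

The generator emulates the purified-enzyme assays: the two sampling
schedules, 10 µM initial phytoene, 0.83 µM enzyme, and proportional
Gaussian measurement noise (`cv = 0.1` by default, the standard error
structure of HPLC peak quantification), truncated at zero with a 0.01 µM
reporting floor mirroring detection-limit censoring. The noise model is a
package choice — the original study states none.

Two kinetic archetypes are shipped as `scenario_preset()`s, both strictly
inside the fitting bounds. The fast archetype
($k_{cat} = 0.02, 0.03, 0.03, 0.012\,s^{-1}$) reproduces the reported
fast-enzyme phenomenology: early intermediates maximal around 20 min, the
terminal product plateauing after ~60 min, phytoene largely consumed
within the first hour. The slow archetype
($k_{cat} = 4, 6, 6, 3 \times 10^{-4}\,s^{-1}$) converts under a fifth of
the phytoene in two hours, so the two presets differ by more than the
factor-5 depletion ratio asserted in the tests. What the presets do *not*
emulate: replicate structure (none is stated), expression-level
differences between enzymes, and any isomer heterogeneity.

The in vivo surrogate (`in_vivo_scenario()`) adds a constant zeroth-order
phytoene influx (a minimal phytoene-synthase stand-in; 1.2e-4 µM/s over
48 h ≈ 21 µM total flux) and, optionally, irreversible Michaelis–Menten
cyclisation branches along the canonical topology (neurosporene →
β-zeacarotene → dihydro-β-carotene; lycopene → γ-carotene → β-carotene;
didehydrolycopene → torulene → dehydro-β-carotene), with user-set
$V_{max}/K_m$ per branch (defaults 2e-4 µM/s and 5 µM, chosen to compete
visibly with desaturation). No cyclase rate law is given by the source
study, so these simulations are strictly exploratory and excluded from
fitting. Branch sources may be chain species or previously declared
branch products, which is how the two-ring species are reached.

## Quantification

`concentration_from_absorbance()` is plain Beer–Lambert,
$c = A/(\varepsilon \ell)$, reported in µM. `resolve_epsilon()` enforces
the closest-molecule substitution rules: tetradehydrolycopene is always
quantified with didehydrolycopene's coefficient and dehydro-β-carotene
with β-zeacarotene's, each flagged through `surrogate_of`; resolution
never chains. The shipped coefficient table
(`inst/extdata/extinction_coefficients.csv`) contains approximate
literature placeholder values only — the study's own coefficient table is
not available — and every quantitative test supplies explicit values
rather than trusting the file.

`pattern_summary()` censors below the detection limit first (mirroring
HPLC reporting), then computes fractions of total carotene, fractions
among desaturated products (phytoene excluded), and the desaturation ×
cycle concentration grid. Cyclisation preserves the desaturation index
and increments the cycle count, which fixes each cyclised species' grid
cell (e.g. β-carotene at (4, 2), torulene at (5, 1)).

## Degenerate inputs and tie-breaks

* `peak_times()` resolves ties to the earliest sampling time, so a
  constant species "peaks" at $t = 0$.
* A composition entirely below the detection limit yields an empty
  pattern summary (a signal, not an error).
* `enzyme_total = 0` is legal (nothing moves); `initial_phytoene = 0` is
  legal only alongside a positive influx.
* Objective weights are undefined for all-zero species; those species are
  skipped, and under `variance` weighting constant species are skipped
  too.
* Profile grids of one point reduce to a single constrained fit;
  `vary_seed = FALSE` makes profiles of objective-irrelevant parameters
  exactly flat by construction.

## Known limitations

The integrator is specialised to this network family rather than a
general ODE interface. The PSO is single-threaded; ten full protocol runs
take ~15 min on one CPU. SBML export covers species, parameters and
kinetic laws sufficient for cross-simulation but no annotations. And the
identifiability limits described above are a property of the
single-substrate progress-curve design itself — individually measured
binding constants, or assays at several enzyme/substrate ratios, would be
required to pin the sloppy directions.
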