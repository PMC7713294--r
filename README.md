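# carokin

Kinetic modelling of multi-step carotene desaturation by CrtI phytoene
desaturases.

CrtI enzymes convert phytoene into a ladder of increasingly desaturated
carotenes (phytofluene, ζ-carotene, neurosporene, lycopene, and beyond),
and the *pattern* of intermediates an enzyme leaves behind is as
characteristic as its final product. `carokin` is for enzymologists and
metabolic engineers who want to simulate, fit, and interrogate that
behaviour quantitatively from HPLC time-course data.

At its core is a mass-action reaction network with explicit
enzyme–substrate/product binding. For an *n*-step chain:

    E + S_i  <=>  ES_i          (k_f[i], k_r[i])     i = 0 … n
    ES_i     -->  E + S_{i+1}   (k_cat[i])           i = 0 … n−1

Every chain species — including the terminal product — competes for free
enzyme; the terminal complex `ES_n` has no catalytic outflow (a dead-end,
product-inhibition complex). Derived constants are `K_d = k_r/k_f` and
`K_m = (k_r + k_cat)/k_f`; over the standard fitting bounds
(`k_f ∈ [0.1, 1] µM⁻¹s⁻¹`, `k_r ∈ [1, 10] s⁻¹`) the admissible K_d span
is exactly 1–100 µM. The stiff ODEs are integrated by a built-in
L-stable SDIRK3(2) solver with analytic Jacobian; rate constants are
estimated by a bounded particle swarm (2000 iterations, swarm 50,
constriction coefficients) minimising mean-square-weighted least squares.

The package also provides:

* HPLC quantification via Beer–Lambert and molar extinction coefficients,
  with the closest-molecule surrogate rules (tetradehydrolycopene →
  didehydrolycopene, dehydro-β-carotene → β-zeacarotene);
* carotene pattern summaries: fractions of total and of desaturated
  products, and the desaturation × cycle concentration grid;
* a synthetic-assay generator (sampling schedules, proportional HPLC
  noise, detection-limit censoring, fast/slow kinetic archetypes, an
  in-vivo-like scenario with phytoene influx and lycopene-cyclase
  branches) plus a parameter-recovery benchmark harness;
* SBML Level 3 export, CSV/JSON round-tripping, and a small CLI.

## Worked example

```r
library(carokin)

net <- build_network(4)
sc  <- scenario_preset("fast_archetype")
tc  <- simulate_timecourse(sc$network, sc$true_params, sc$assay)
round(as.data.frame(tc)[c(1, 6, 8, 10), ], 3)
#>    time_min phytoene phytofluene zeta_carotene neurosporene lycopene
#> 1         0   10.000       0.000         0.000        0.000    0.000
#> 6        20    1.714       4.257         2.628        1.228    0.173
#> 8        40    0.192       1.696         2.630        3.821    1.661
#> 10      120    0.000       0.007         0.044        1.233    8.717

peak_times(tc)
#>      phytoene   phytofluene zeta_carotene  neurosporene      lycopene
#>             0            20            30            60           120
```

The fast archetype reproduces the fast-enzyme phenomenology: phytoene is
largely consumed within the first hour, the early intermediates peak
around 20–30 min, and the terminal product accumulates to a plateau —
87% of the desaturated products at 120 min:

```r
pattern_summary(unlist(tc[10, -1]), detection_limit = 0.01)
#> Carotene pattern (total 9.993 µM)
#>   fraction of total carotene:
#>     zeta_carotene             0.4%
#>     neurosporene             12.3%
#>     lycopene                 87.2%
#>   ...
```

Refitting noisy synthetic data recovers the catalytic constants (truth:
0.02, 0.03, 0.03, 0.012 s⁻¹) even with a deliberately short swarm run:

```r
noisy <- generate_timecourse(scenario_preset("fast_archetype",
                             noise = noise_spec(cv = 0.1, seed = 4)))
fit <- fit_pso(net, list(list(assay = sc$assay, timecourse = noisy)),
               fit_config(net, iterations = 150, swarm_size = 20, seed = 1))
fit
#> Particle-swarm fit (seed 1, 150 iterations, swarm 20)
#>   objective : 0.406315
#>   derived constants (per complex):
#>  step    K_d    K_m   k_cat
#>     1  3.236  3.255 0.01842
#>     2  8.444  8.498 0.02782
#>     3 10.020 10.066 0.03068
#>     4 11.717 11.737 0.01505
#>     5  5.052     NA      NA
```

Binding constants (`K_d`) are far less identifiable than catalytic ones
from single-substrate progress curves; see `profile_identifiability()`
and the methods vignette (`vignettes/carotene-desaturation-kinetics.Rmd`)
for the quantitative story.

## Extinction coefficients

`inst/extdata/extinction_coefficients.csv` ships **placeholder**
literature values so the quantification pipeline is runnable end to end;
replace it with a curated table for real quantitative work. The surrogate
rules are enforced in code regardless of the table's contents.
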