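# tgkinetics

Solid-state decomposition kinetics and shelf-life estimation from
thermogravimetric (TG) data, in R.

Thermal stability is a routine concern for active pharmaceutical
ingredients: the first irreversible decomposition step bounds how long a
compound can be stored. `tgkinetics` implements the standard accelerated
workflow for single-step solid-state decomposition governed by

    dα/dt = k(T) f(α),     k(T) = A exp(−Ea / RT),

where α = (m0 − m_t)/(m0 − m_f) is the conversion degree computed from TG
mass readings and f(α) is a solid-state reaction model. It is written for
thermal-analysis practitioners and method developers who want the whole
chain — data ingestion, model-free and model-based kinetics, and Arrhenius
extrapolation — as composable, tested functions rather than spreadsheet
steps.

Four components:

* **Kinetic model registry** — the twelve classical integral forms
  g(α) = kt + k0 (nucleation F1, Avrami–Erofeev Am2/Am3/Am4, autocatalytic
  Au, contraction R1/R2/R3, diffusion D1–D4 incl. Ginstling–Brounshtein),
  each with g, its inverse, and f.
* **Nonlinear isoconversional (Vyazovkin) analysis** — Ea(α) from curves at
  several heating rates by minimising the pairwise ratio objective
  ΣᵢΣ_{j≠i} [I(E,T_α,i) βⱼ]/[I(E,T_α,j) βᵢ] ≥ n(n−1), with the temperature
  integral I(E,T) = (E/R)·p(x) evaluated through the third-degree
  Senum–Yang approximation (relative error < 1e-5 % vs quadrature).
* **Fixed-hidden-weight MLP ensemble** — one hidden neuron per kinetic
  model, hidden weights pinned to each model's linearised fit (k, k0),
  hidden activation = the model's g⁻¹, output weights solved in closed form
  by the pseudo-inverse w2 = (BᵀB)⁻¹Bᵀα; |w2|-normalised contributions and
  per-model residuals rank the mechanisms.
* **Shelf life** — per-model Arrhenius fits of ln k vs 1/T across the
  isothermal temperatures, extrapolated to storage temperature;
  t90 = g(0.10)/k(T), the time to 10 % conversion.

Synthetic TG generators (isothermal, nonisothermal ODE/integral-form, and
multi-step mass curves with stoichiometry derived from a molecular
formula) make every stage testable by parameter recovery; no instrument
data is required.

## Worked example

Model-free activation energy from four simulated heating-rate curves
(generated from the R2 area-contraction model with Ea = 100 kJ/mol,
A = 1e10 min⁻¹):

```r
library(tgkinetics)

ar <- arrhenius_spec(Ea = 100e3, lnA = log(1e10))
curves <- lapply(c(5, 7.5, 10, 12.5),
                 function(b) simulate_nonisothermal("R2", ar, beta = b))
isoconversional_profile(curves)
#> <isoconversional_result: 9 levels, 4 heating rates>
#>  alpha Ea_kJ_mol objective   dispersion at_boundary
#>    0.1 100.00551        12 5.768238e-05       FALSE
#>    0.2  99.99398        12 1.618869e-05       FALSE
#>    0.3  99.99382        12 2.804897e-05       FALSE
#>    0.4  99.99899        12 1.694544e-06       FALSE
#>    0.5  99.99399        12 1.212634e-05       FALSE
#>    ...
```

The profile is flat at the generating 100 kJ/mol (recovery error < 0.01 %),
the objective sits at its analytic floor n(n−1) = 12, and the dispersion of
the pairwise ratio terms is ~1e-5 — the consistency diagnostic reported per
level.

Ensemble combination and shelf life from four simulated isothermal runs
(R1 linear-contraction model, Ea = 95.6 kJ/mol, noise sd 0.002, 60 min at
158/160/162/164 °C):

```r
ar_iso <- arrhenius_spec(95.6e3, lnA_for_isothermal("R1", 95.6e3, 164, 0.9, 60))
iso <- lapply(seq_along(c(158, 160, 162, 164)), function(i)
  simulate_isothermal("R1", ar_iso, c(158, 160, 162, 164)[i],
                      times = 0:60, noise_sd = 0.002, seed = i))
combos <- lapply(iso, combination_report)
combos[[1]]
#> <combination_result at 431.15 K: residual 2.66e-06>
#>  model        k         k0  residual       w2 contribution
#>     R1 0.010408  0.0001399 3.121e-06  0.93478     0.403651
#>     R2 0.006385 -0.0130857 1.198e-04  0.42137     0.181953
#>     R3 0.004569 -0.0123714 2.009e-04 -0.35962     0.155287
#>     ...

slt <- shelf_life_table(combos)
slt[slt$model %in% c("R1", "R2", "R3"),
    c("model", "Ea_kJ_mol", "ln_A", "t90_158C_h", "t90_25C_years")]
#>  model Ea_kJ_mol  ln_A t90_158C_h t90_25C_years
#>     R1     95.18 21.99     0.1602          2.55
#>     R2    137.10 33.18     0.1351        396.01
#>     R3    153.47 37.41     0.1274       2864.61
```

The generating model R1 has the smallest single-model residual and the
largest contribution, and its row recovers the generating parameters
(Ea 95.18 vs 95.60 kJ/mol truth; t90(25 °C) 2.55 vs 2.69 years truth).
Rows for other models show what mis-specification does to an extrapolation:
their Arrhenius slopes are artefacts, which is why mechanism selection
(residual ranking, contributions) precedes any shelf-life claim.

## The analysis workflow

Numbered drivers under `analysis/` run the full synthetic study and write
tables under `results/` (raw simulated traces go to `scratch/fixtures/`):

```sh
Rscript analysis/01_simulate.R     # synthetic TG study data (both arms)
Rscript analysis/02_vyazovkin.R    # nonisothermal arm: Ea(alpha) profile
Rscript analysis/03_combine.R      # isothermal arm: per-temperature ensembles
Rscript analysis/04_shelf_life.R   # Arrhenius + t90 table + cross-arm check
```

Step 1 builds three-stage mass curves (dehydration → N-dealkylation → ring
decomposition) for a hydrated Mn-porphyrin-like sample — stage mass-loss
fractions derived from the molecular formula — plus the four isothermal
runs. Steps 2–4 read those files back through the TG parser, so the
workflow exercises the same I/O path an instrument export would take.

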