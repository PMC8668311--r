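---
title: "Solid-state decomposition kinetics, model ensembles, and shelf life from TG data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solid-state decomposition kinetics, model ensembles, and shelf life from TG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgkinetics)
```

## The problem

Thermogravimetry (TG) records sample mass under a controlled temperature
program. For a drug substance, the first irreversible mass-loss step bounds
its solid-state stability: once that step's kinetics are known at
accelerated temperatures, the Arrhenius law extrapolates the rate to
storage temperature, and the t90 shelf life (time to 10% conversion)
follows. `tgkinetics` implements that chain for single-step solid-state
decomposition: conversion-degree computation from mass curves, model-free
(isoconversional) activation-energy estimation from multi-heating-rate
ramps, a fixed-weight neural-network ensemble of classical kinetic models
for isothermal holds, and the Arrhenius/t90 extrapolation. Because raw
instrument traces for the motivating compound class (cationic Mn-porphyrin
antioxidant drug candidates, which lose ethyl chloride by N-dealkylation as
their first degrading step) are generally not published, the package ships
forward simulators that generate TG data with the same statistical
structure, so every stage is testable by parameter recovery.

## The rate law and the model registry

Solid-state decomposition is modelled as

$$\frac{d\alpha}{dt} = k(T)\, f(\alpha), \qquad
  k(T) = A \exp\!\left(-\frac{E_a}{R T}\right),$$

where $\alpha \in [0,1]$ is the conversion degree, computed from masses as
$\alpha = (m_0 - m_t)/(m_0 - m_f)$. The reaction model $f$ encodes the
mechanism; its integral form $g(\alpha) = \int_0^\alpha f(u)^{-1} du$
linearises an isothermal run as $g(\alpha) = k t + k_0$.

The registry (`kinetic_models()`) holds the twelve classical forms, in a
fixed order so that downstream weight vectors are comparable across runs:
first-order nucleation F1; Avrami–Erofeev Am2/Am3/Am4 and the autocatalytic
(logistic) form Au; geometric contraction R1 (linear), R2 (area), R3
(volume); and diffusion D1–D4 (one/two/three dimensions and
Ginstling–Brounshtein). Each entry carries $g$, its inverse, $f$, and the
domain on which they are finite. The ensemble default is the ten-model
subset Am2, Am4, Au, R1, R2, R3, D1–D4.

Numerical choices worth knowing:

* D2 and D4 have no closed-form inverse; they are inverted by bracketed
  root finding at tolerance 1e-14. Near $\alpha = 0$ their integral forms
  are differences of $O(1)$ terms and cancel catastrophically (the true
  value is $\sim c\,\alpha^2$), so below $\alpha \approx 10^{-3}$ the
  inverse switches to the series $\alpha = \sqrt{y/c}\,(1 - d\sqrt{y/c}/2)$
  with the exact quadratic/cubic coefficients ($c = 1/2, d = 1/3$ for D2;
  $c = 1/9, d = 4/9$ for D4).
* Transforms that diverge at an endpoint (F1, Am, Au at 1; Au also at 0)
  are clipped by a configurable `clip_eps` (default 1e-6) before $g$ is
  applied; models finite on the closed interval are never clipped, so their
  fits are exact on exact data.
* The autocatalytic Au form $g(\alpha) = \ln(\alpha/(1-\alpha))$ is
  negative below $\alpha = 0.5$; under the convention $t_{90} = g(0.10)/k$
  its shelf life is ill-defined (negative), and the package reports `NA`
  for Au rather than a sign-flipped number.

## Nonisothermal arm: nonlinear isoconversional analysis

With curves recorded at $n$ heating rates $\beta_i$, the temperature at
which curve $i$ crosses level $\alpha$ is $T_{\alpha,i}$ (monotone linear
interpolation; first crossing under noise). Writing the temperature
integral

$$I(E, T) = \int_0^T e^{-E/(R T')} dT' = \frac{E}{R}\, p(x), \quad
  x = \frac{E}{R T},$$

the model-free estimate of $E_a(\alpha)$ minimises the pairwise-ratio
objective

$$\Phi(E) = \sum_{i=1}^{n} \sum_{j \ne i}
  \frac{I(E, T_{\alpha,i})\, \beta_j}{I(E, T_{\alpha,j})\, \beta_i},$$

which by the AM–GM inequality is bounded below by $n(n-1)$, with equality
exactly when all ratios equal one — the isoconversional consistency
condition. Minimisation is bounded Brent search on $[10, 400]$ kJ/mol to
0.01 kJ/mol; a minimum within ~20 J/mol of a bound raises a boundary flag.
The per-level *dispersion* reported alongside $E_a(\alpha)$ is the sample
standard deviation of the $n(n-1)$ ratio terms at the optimum (each ideally
1); this definition was an open choice and is pluggable in principle, but
it is what the profile reports.

$p(x)$ uses the standard third-degree Senum–Yang rational approximation

$$p(x) = \frac{e^{-x}}{x}\cdot
  \frac{x^2 + 10x + 18}{x^3 + 12x^2 + 36x + 24},$$

whose relative error against adaptive quadrature of
$\int_x^\infty e^{-u} u^{-2} du$ is below $10^{-5}$ percent for the $x$
range of interest (the package's quadrature oracle,
`p_exact_quadrature()`, evaluates the integral on a shifted, exponentially
scaled integrand so nothing underflows). A corrupted variant of this
formula with `368x` in place of `36x` circulates in parts of the applied
literature; it deviates by roughly 13 percent and is selectable
(`variant = "printed"`) purely for comparison. The temperature-integral
lower limit is 0 K, consistent with the $p(x)$ transform.

## Isothermal arm: the fixed-hidden-weight MLP ensemble

The ensemble is a single-hidden-layer perceptron whose hidden weights are
*not trained*: hidden neuron $i$ corresponds to kinetic model $i$, and its
incoming weight and bias are the slope and intercept $(k_i, k_{0,i})$ of
that model's linearised fit $g_i(\alpha) = k_i t + k_{0,i}$ (ordinary least
squares of $g_i(\alpha_\mathrm{exp})$ on time). The hidden activation is
the model's $g^{-1}$, clipped to $[0,1]$, so hidden state $i$ at time $t$
is exactly model $i$'s predicted conversion — monotone, approaching one
late in the run. Stacking the states gives the matrix $B$ (rows = times,
columns = models, registry order). The output layer is linear and solved
in closed form by the pseudo-inverse,

$$w_2 = (B^\top B)^{-1} B^\top \alpha_\mathrm{exp},$$

minimising $\lVert B w_2 - \alpha_\mathrm{exp}\rVert^2$. When the
normal-equations condition number exceeds 1e10 the minimum-norm SVD
solution is used instead (the explicit inverse is numerically fragile on
near-collinear model columns) and the condition number is reported. $w_2$
is unconstrained — negative entries are legitimate — and per-model
contributions are reported as $|w_{2,i}| / \sum_j |w_{2,j}|$. Whether the
hidden states should be clipped to $[0,1]$ and whether contributions
should be raw, absolute, or squared were open choices; clipping and
absolute-value normalisation are this package's policy.

### What contribution attribution can and cannot do

A caveat that the package's own acceptance experiments quantify: the ten
model curves are similar S-shapes, so $B$ is near-collinear
($\kappa(B^\top B) \sim 10^{10}$). On noise-free single-mechanism data the
ensemble attributes all weight to the generating model exactly. Under
realistic noise (sd 0.002 in $\alpha$), however, unregularised least
squares is free to move weight along near-null directions, and the
generating model's *contribution* is often not the largest — mixtures of
other columns reconstruct the noisy curve equally well. The *single-model
residual ranking* (`per_model_residuals()`) identifies the generating
mechanism reliably in the same conditions. Conclusions about mechanism
should therefore rest on the residual ranking, with contributions read as
a description of the fitted combination, not as evidence of mechanism.
Ridge-type stabilisation would change this trade-off but is deliberately
out of scope: the method's defining feature is the closed-form
pseudo-inverse.

## Shelf life

Per model, the rate constants fitted at each isothermal temperature are
regressed as $\ln k$ on $1/T$ (slope $-E_a/R$, intercept $\ln A$, $A$ in
min⁻¹ throughout since time is in minutes), and

$$t_{90}(T) = \frac{g(0.10)}{k(T)}$$

is reported in minutes, hours, and years (1 year = 525,600 min). The
fitted intercept $k_0$ is deliberately excluded from $t_{90}$: it absorbs
experimental offsets (heat-up, baseline) that should not extrapolate to
storage conditions. Query temperatures default to 158 °C (the accelerated
condition, reported in hours) and 25 °C (storage, in years). The study
summary's cross-protocol check compares the *dominant* model's $E_a$
(largest mean contribution across temperatures) with the mean of the
isoconversional profile; a plain mean over all ten models would be
meaningless because structurally misfit models carry arbitrary Arrhenius
slopes.

## Synthetic data: what it emulates, what it does not

The generators produce three kinds of records:

* `simulate_isothermal()` — closed-form $\alpha(t) = g^{-1}(\min(kt,
  g(\alpha_\mathrm{max})))$ plus i.i.d. Gaussian noise on $\alpha$,
  clipped to $[0,1]$.
* `simulate_nonisothermal()` — integrates $d\alpha/dT = (1/\beta) k(T)
  f(\alpha)$ with a stiff-safe adaptive integrator (lsoda, rtol 1e-8) from
  $\alpha_0 = 10^{-8}$, or equivalently evaluates the integral form
  $g(\alpha) = g(\alpha_0) + (A/\beta) I(E,T)$; the two routes agree to
  better than $10^{-3}$ in $\alpha$ and serve as mutual oracles.
* `simulate_tg_mass_curve()` — superposes stages, $m(T) = m_0 (1 -
  \sum_s \ell_s \alpha_s(T))$, plus Gaussian mass noise. The packaged
  three-stage recipe (`mn_porphyrin_stages()`) emulates a hydrated
  Mn-porphyrin-like sample: the water and ethyl-chloride loss fractions
  are derived from the molecular formula of the synthetic octahydrate by a
  molar-mass routine, never hard-coded, and the stage prefactors are set
  from requested step-midpoint temperatures via the integral form rather
  than by hand.

Default study conditions mirror the accelerated design the analysis
expects: four isotherms at 158/160/162/164 °C sampled once per minute for
60 min, and four ramps at 5/7.5/10/12.5 °C/min over 30–600 °C on a 0.5 K
grid, giving $x = E/RT \approx 25$–27. The default isothermal prefactor is
set by the requirement that the accelerated runs must *not* run to
completion (`lnA_for_isothermal()` solves $g(0.9) = k\,t_\mathrm{end}$ at
the hottest temperature): a saturated curve has a flat tail that biases
the linearised fits. Noise defaults (sd 0.002 on $\alpha$; 1 µg on mass)
are a choice — the motivating instrument's noise magnitude is not
published — and are exposed as arguments.

The generators do **not** emulate heat/mass-transfer lag, sample-size
effects, buoyancy drift, autocorrelated baseline error, or kinetic
compensation. Passing recovery tests on this synthetic data therefore
demonstrates the correctness of the estimators under the stated noise
model, not robustness to every instrument artifact.

One practical pitfall the conversion step guards against: the default
$m_0/m_f$ baseline is taken at the analysis-window boundaries, which is
right for a completed step isolated from a dynamic curve, but silently
*renormalises* an isothermal run that ends mid-step (every zero-order run
would fit $k = 1/t_\mathrm{end}$ regardless of temperature). When the
step's plateau mass is known — in practice from a complete dynamic run —
pass it as `mf` (or `iso_mf` in the study config); the resulting curve is
flagged partial and keeps its rate information.

## Problem sizes and determinism

All analyses here are small and deterministic: nine-level profiles over
four curves of ~1,100 points run in well under a second, and the whole
synthetic study (simulation, both arms, shelf-life table) completes in a
few seconds. Every stochastic generator takes an explicit integer seed and
identical seeds give bit-identical curves; pipeline reruns with the same
config and seed produce byte-identical CSV reports.

## Known limitations

* Contribution-based mechanism identification is unreliable under noise
  (see above); use the residual ranking.
* The isoconversional arm assumes every curve crosses each grid level
  inside its window; partial curves raise errors naming the offending
  curve rather than extrapolating.
* Error propagation is limited to the dispersion statistic and the
  Arrhenius fit diagnostics; no confidence intervals on $t_{90}$.
* Flynn–Wall–Ozawa, KAS, and Friedman methods, Šesták–Berggren models,
  humidity/ICH accelerated-stability modelling, and vendor binary formats
  are out of scope.
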