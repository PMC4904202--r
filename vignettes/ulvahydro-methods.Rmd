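---
title: "Methods: robust-design analysis of Ulva hydrolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust-design analysis of Ulva hydrolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulvahydro)
library(dplyr)
```

`ulvahydro` analyses thermochemical acid hydrolysis of green macroalgae
(*Ulva*) as a biorefinery feedstock. The pipeline runs from a 16-run
mixed-level designed experiment (temperature, treatment time, sulfuric-acid
concentration, solid load) through carbohydrate release statistics,
robust-design factor ranking, regression diagnostics, hydrolysate density
sensing, and constraint-based prediction of fermentation product yields.
This vignette explains each model, its assumptions, and the numerical
choices behind the implementation.

## The designed experiment

The packaged design (`ulva_design()`) crosses three 3-level factors
(temperature 100/121/134 degC, time 30/45/60 min, solid load 5/15/25 % w/v)
with one 4-level factor (acid 0/0.5/2/5 % w/v) in 16 runs. Such a
mixed-level array cannot be fully orthogonal (neither 9 nor 12 divides 16),
so per-level run counts vary between 4 and 6 and factor-level means are not
perfectly decoupled. Two consequences run through the whole package:

* every per-level average uses the *actual* number of runs at that level,
  never `16 / #levels`;
* a factor with no planted effect still shows a small apparent sensitivity
  because the other factors are not balanced within its levels. On this
  array the contamination range is about 4 dB for a 30 dB planted effect,
  which is why recovery tests assert rank ordering and dominance rather
  than exact zeros.

## Larger-the-better signal-to-noise analysis

Each outcome (four monosaccharide concentrations, total released mass,
percent yield, hydrolysate density) is scored per run by the Taguchi
larger-the-better statistic

$$R = -10\,\log_{10}\Bigl(\tfrac{1}{\#Reps}\sum_{Rep} m_{Rep}^{-2}\Bigr),$$

in decibels over the replicates of that run. Sensitivity of an outcome to a
factor is the range $\Delta = \max_L \bar R(L) - \min_L \bar R(L)$ of its
per-level averages; factors are ranked by descending $\Delta$ (rank 1 =
most influential) and the optimum setting per factor is the level with the
largest average $R$. Ties are broken deterministically (declared factor
order for ranks, lower level for optima) and flagged.

Numerical choices:

* **Measurement floor** (default `0.001` in the outcome's unit): values
  below the floor are raised to it before squaring reciprocals, so a run
  with both duplicates at the detection floor scores exactly $-60$ dB
  instead of $-\infty$. The floor is a visible argument everywhere it is
  used.
* **Duplicate reconstruction.** The packaged tables summarise duplicates as
  mean and sample standard deviation. For two replicates the summary is
  exactly invertible: $x_{1,2} = \bar x \pm s/\sqrt 2$ (sample sd,
  $n-1$ denominator). A reconstructed replicate that would be negative is
  clamped at zero and flagged. Reconstruction recovers the published
  headline ratios (46.79, 47.17, 97.21 dB) exactly; cells whose printed
  summaries are small relative to their 1-decimal rounding (yields under
  1%) cannot be reproduced beyond a few tenths of a dB, and two printed
  cells are carried as documented suspects (`ulva_fixture_notes()`).
* All ratios are computed at full precision and rounded only for
  presentation.

## Percent yield

Released mass is the sum of the four quantified sugar concentrations
(ug/ml) times the reaction volume times an effective dilution factor, and

$$\text{yield\%} = \frac{\text{Total (ug)}}{m_{dw}\,(\text{mg}) \times 1000}
\times 100 .$$

The dilution factor defaults to 2.7: the packaged totals are uniformly
2.7x the concentration sums (exactly on run 3), consistent with
post-neutralisation dilution of the nominal 1 ml reaction volume. It is a
configuration parameter with its provenance documented, never a constant
buried in a formula. Sugars other than rhamnose, glucose, xylose and
glucuronic acid are ignored as negligible.

## PLS1 regression with cross-validation

Each outcome is regressed on the four process factors by single-response
partial least squares: sequential extraction of latent components
maximising covariance with the response. Predictors are autoscaled
(centred, unit variance) and the response centred; coefficients are
reported on both the standardised and raw scales. With as many components
as full-rank predictors the fit equals ordinary least squares, which is the
oracle the tests hold it to.

* **Component count** is chosen by minimum leave-one-out RMSECV over 1-4
  when not given; the experiment is too small for a separate test set, so
  refit leave-one-out cross-validation is the only validation used.
* **Diagnostics.** $\mathrm{RMSECV} = \sqrt{\sum_i (\hat y_{(-i)} -
  y_i)^2 / n}$, relative error $100\,\mathrm{RMSECV}/\bar y$, and
  $\mathrm{RPD} = s_y / \mathrm{RMSECV}$ ($n-1$ denominator), with the
  conventional bands unusable (< 1.5), distinguish high/low (1.5-2.0),
  quantitative (2.0-2.5), excellent (>= 2.5), closed on the left: a model
  at exactly 1.5 is credited with distinguishing ability. The identity
  $\mathrm{RPD}\cdot\mathrm{RMSECV} = s_y$ holds by construction and is
  asserted in the tests.
* **Calibration vs cross-validation error.** The fit object also carries
  the calibration RMSE (training residuals). For these data the published
  error statistics of the re-assessed reduced models coincide with the
  calibration RMSE of one-component fits, not with a refit leave-one-out
  error, which at n = 16 is systematically larger; the package reports
  both quantities so either comparison is explicit.
* **Variable selection** uses the Martens uncertainty test: jackknife
  variance of each standardised coefficient over the leave-one-out
  segments, $s^2 = \frac{n-1}{n}\sum_i (b_{(-i)} - b)^2$, with a two-sided
  t criterion at 95%. It is deterministic given the data. Note that on
  this design the *standardised* planted effect of solid load exceeds that
  of acid (the design spans 20 percentage points of solids but only 5 of
  acid), so detection power is highest for solids.
* A `log10` transform with the same 0.001 floor is available for the
  strongly right-skewed concentration outcomes (four orders of magnitude
  across runs); both transformed and untransformed analyses are supported,
  untransformed being the default.

## Resonating-micromembrane density sensing

A circular tensioned membrane (Young's modulus 130 GPa, pre-calibrated
strain $4\times10^{-6}$, film density 2650 kg m$^{-3}$, film volume
0.59 pL) vibrates at

$$f_{mn} = \frac{\alpha_{mn}}{2\pi R}\sqrt{\frac{Y\varepsilon}{\rho}},$$

inversely proportional to the square root of the effective mass density. A
deposited droplet (density $\rho_1$, volume $V_1$) adds mass and shifts
every mode downward. The mode factors $\alpha_{mn}$ are back-calibrated
from the measured dry frequencies (82 kHz for the calibration mode (3,4))
rather than from Bessel zeros, because the nominal device geometry
over-determines the analytical factors.

**Identifiability.** Pure mass loading senses only the product
$\rho_1 V_1$: any number of modes then yields one effective equation, and
density and volume cannot be separated. The package therefore models
droplet-mode coupling with a coverage factor
$\beta_{mn}(V_1) = 1/(1 + \gamma_{mn} V_1 / V_f)$: a larger droplet spreads
beyond the high-displacement region of a fine-structured mode, and does so
faster for modes with larger coverage rate $\gamma$. The added modal mass
is $\beta_{mn}\rho_1 V_1$, giving the small-load limit
$\Delta f / f_{dry} \to \tfrac12 \rho_1 V_1 / (\rho_f V_f)$ for a
full-coverage mode. Two modes with distinct $\gamma$ make $(\rho_1, V_1)$
jointly identifiable; with one mode the inversion requires a known volume
and refuses otherwise. The composite density
$(\rho_f V_f + \rho_1 V_1)/(V_f + V_1)$ is reported as the volume-weighted
effective density of the loaded device.

**Inversion** is damped Gauss-Newton on $(\log\rho_1, \log V_1)$
(positivity by parameterisation), initialised from the closed-form
two-mode solution, relative tolerance $10^{-10}$, at most 100 iterations;
residuals are relative frequency errors. Zero shifts return $V_1 = 0$ with
the density flagged unidentifiable. Spectral width and dissipation are
ignored; only average density is used downstream. The simulator applies
multiplicative gaussian noise to the frequency *shifts*, matching how
shift uncertainty is quoted for such devices; at 0.1% shift noise the
median density error over the density span seen in the experiments
(1000-1034 kg m$^{-3}$) stays under 2%.

## Flux balance and flux variability analysis

Fermentation yield prediction is the standard two-stage linear programme.
Stage one maximises the growth flux subject to steady-state mass balance
$S v = 0$ and flux bounds ($[-\infty,\infty]$ for bidirectional,
$[0,\infty]$ for unidirectional reactions, with infinities capped at
1000 mmol gDW$^{-1}$ h$^{-1}$); stage two fixes growth at its optimum and
minimises/maximises the target transporter flux (ethanol, acetone,
butanol). An organism with maximal growth below $\varepsilon = 10^{-5}$
h$^{-1}$ is non-viable and scores zero yields.

* **Media constraint.** Total media consumption is capped at
  1 g gDW$^{-1}$ h$^{-1}$, split across usable components in proportion to
  their mass fractions; the molar uptake cap of a component is its mass
  allowance divided by its molecular mass. Uptake is the negative flux
  direction of an exchange reaction; components without a transporter in
  the model are dropped with a message.
* **Unit bridge.** With that normalisation, a product flux of $v$
  mmol gDW$^{-1}$ h$^{-1}$ corresponds to $v \times MW$ g product per kg
  of feedstock-derived medium.
* **Growth fixation.** The LP optimum carries float error, so stage two
  fixes growth within a $10^{-9}$ absolute band; if even that is
  infeasible the bound relaxes to $(1 - 10^{-6})\,\mathrm{MaxGrowth}$ with
  a message. Only objective values are contract outputs - flux vectors at
  degenerate optima are not unique.
* **Solver.** The LPs are solved by a compact two-phase dense simplex
  with Bland's anti-cycling pivoting rule, written for this package. The
  equality-fixed, highly degenerate FVA problems are exactly the regime
  where heuristic pivoting stalls or cycles; Bland's rule trades speed
  (irrelevant at tens of reactions) for unconditional termination. The
  solver is validated in the test suite against an independent exhaustive
  vertex-enumeration oracle on hundreds of random bounded networks.
* **Scope.** Genome-scale models of the fermenting organisms are opaque
  inputs: the JSON model format loads them if supplied, but packaged
  analyses run on small networks with closed-form optima. The published
  genome-scale yield panels depend on unpublished model versions and are
  represented qualitatively (viability-gated zero rows, glucose-driven
  yield ordering) by `toy_ulva_fermenter()`, a synthetic stand-in whose
  ATP yield comes only from glucose and xylose fermentation.

## Synthetic data

All randomised studies draw from generators that are pure functions of
their parameters and a seed:

* `simulate_doe()` plants per-level outcome multipliers on the 16-run
  array with multiplicative log-normal replicate noise (concentrations
  span four decades, so proportional noise is the realistic default;
  additive gaussian is available). The default effect sizes mirror the
  experiment's structure - acid dominant and non-monotone with its peak
  at the 2% level, solids second, time weak, temperature weakest - and
  give deterministic realized sensitivities of roughly 31/15/9/5 dB, so
  the planted ordering survives 5% replicate noise with a wide margin.
* `simulate_pls_data()` plants the percent-yield process equation
  (intercept 6.44; coefficients 0.04, -0.004, 0.7, -0.60 for temperature,
  time, acid, solids) with gaussian noise sd 2. At n = 16 the time
  coefficient is two orders of magnitude below its standard error, so
  recovery assertions apply to the detectable coefficients; this is a
  property of the planted model, not of the fitter.
* `simulate_resonator()` evaluates the droplet forward model exactly and
  perturbs the shifts multiplicatively.
* `random_toy_network()` draws sparse stoichiometries with finite bounds
  containing zero flux, so every generated LP is feasible and bounded -
  the property the vertex-enumeration oracle needs.

What the generators do *not* emulate: instrument drift and calibration
error in the chromatography, correlated replicate errors, non-linear
factor interactions, genome-scale network structure, and resonator
spectral lineshapes. Passing recovery tests therefore demonstrate that the
estimators invert their own forward models at realistic signal-to-noise,
not that the laboratory data meet those models.

## Problem sizes and runtimes

The test suite runs the full printed-table reproductions (16 runs), 200
random networks of up to 8 reactions against the vertex oracle, 200
seeded PLS replicates at n = 16, 100 seeded design-recovery replicates,
and 50 seeded density inversions - a few minutes end to end on one core.
These sizes were chosen so the brute-force oracles (vertex enumeration is
exponential in network size) remain exact references.

## Known limitations

* The effect model behind the S/N analysis is additive in dB; strong
  factor interactions would be attributed to main effects.
* With 16 runs and duplicate measurements, all regression diagnostics have
  wide sampling variability; RPD bands should be read as qualitative.
* The droplet coverage model is a two-parameter phenomenology chosen for
  identifiability, not a solved fluid-structure problem; its $\gamma$
  values are calibration inputs.
* The media constraint splits the mass budget proportionally; a shared
  unallocated budget would give the organism more freedom and generally
  higher growth.
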