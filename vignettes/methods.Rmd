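---
title: "Methods: coupled land-use simulation and ecosystem-service valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled land-use simulation and ecosystem-service valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucesv)
```

`lucesv` implements a complete modelling chain for scenario-based land-use
change simulation and ecosystem-service valuation on categorical rasters:
grey and Markov demand forecasting, neural-network suitability mapping, a
constrained cellular automaton (CA) for spatial allocation, and the
corrected equivalent-factor method for ecosystem-service value (ESV)
accounting. A seeded synthetic-landscape generator makes every stage
testable end to end without any proprietary data. This vignette documents
the models, the default parameters and their rationale, the numerical
choices, and the known limitations.

## 1. The modelling chain

The pipeline (`run_pipeline()`) follows the standard coupled framework:

1. **Demand**: per-class area targets for a horizon year, forecast from a
   short historical series.
2. **Suitability**: a per-cell, per-class occurrence probability surface
   learned from driving factors.
3. **Allocation**: a CA distributes the demanded areas in space under a
   scenario's conversion rules and a restricted (frozen) zone.
4. **Valuation**: the resulting class areas are priced with per-hectare
   coefficients corrected for regional conditions, and the trend between
   the first and horizon year is reported.

### 1.1 GM(1,1) grey forecasting

Land-use area series are short (a handful of survey years), which rules
out most time-series models. The GM(1,1) grey model (`gm11()`) fits an
exponential trend to the *accumulated* series: with
$x^{(1)}(k)=\sum_{i\le k}x^{(0)}(i)$ and background values
$z^{(1)}(k)=\tfrac12\,(x^{(1)}(k)+x^{(1)}(k-1))$, the development
coefficient $a$ and grey input $b$ solve the least-squares problem
$x^{(0)}(k) = -a\,z^{(1)}(k)+b$. The restored series is

$$\hat x^{(0)}(k) = \Bigl(x^{(0)}(1)-\tfrac{b}{a}\Bigr)\,(1-e^{a})\,e^{-a(k-1)},
\qquad \hat x^{(0)}(1)=x^{(0)}(1).$$

We solve the normal equations directly (two unknowns; conditioning is not
a concern at these sizes) and take the analytic $a\to 0$ limit for
constant series. Fits with $|a|\ge 2$ trigger an instability warning, the
usual applicability bound for GM(1,1). Fit quality is graded by the
posterior difference test (`posterior_difference_test()`): the ratio
$C = S_2/S_1$ of residual to data standard deviation and the small-error
probability $P = \Pr(|e-\bar e| < 0.6745\,S_1)$, banded into levels 1–4
by the conventional thresholds, taking the worse of the two bands.

### 1.2 Markov transition projection

`estimate_transition_matrix()` cross-tabulates two dated maps into a
row-stochastic matrix $P$ (absent classes receive identity rows) and
`predict_markov()` advances the area vector, $S_{t+k} = S_t P^k$. Total
area is conserved exactly. `compare_models()` confronts the two
forecasting routes on a held-out year using per-class relative
differences; the pipeline keeps both and records which wins. On the
synthetic scenarios the Markov route often wins — unsurprisingly, since
the generator evolves maps by per-cell transitions, which is exactly the
Markov data-generating process; on tabular survey series with a steady
trend the grey model is typically the better extrapolator.

### 1.3 ANN suitability

`train_suitability_ann()` fits a single-hidden-layer feed-forward network
with softmax output (via `nnet`) mapping min–max normalized driving
factors (`normalize_stack()`) to class membership of sampled cells, so
each cell receives a proper probability distribution over classes.
Defaults: 12 hidden units and 300 epochs, comfortable for up to ~16
factors and 8 classes while keeping training in seconds; a 2% uniform
cell sample is the default training set, which on a $100\times100$ grid
yields 200 training cells and on realistic grids keeps class imbalance
manageable. `screen_factors_logistic()` provides the standard
factor-screening companion: a class-versus-rest logistic regression
scored by the ROC area, computed with the Mann–Whitney rank statistic
(`auc_rank()`); complete separation is detected from the fitted ranking
and reported as AUC 1 with a flag rather than an error.

### 1.4 Constrained cellular automaton

`run_allocation()` distributes integer cell demands under a binary
conversion-rules matrix (`transition_rules()`) and an optional frozen
mask. The per-cell competition score of class $j$ is the product of its
suitability probability, its Moore-neighborhood density (window size 7 by
default, truncated at edges, computed with integral images so each sweep
is $O(\text{cells})$), and a per-class adaptive inertia coefficient. The
next class is drawn by roulette selection rather than argmax, which
preserves landscape heterogeneity. The inertia follows the standard
three-case self-adaptive update on the demand gap $D =$ demand $-$
allocated: unchanged while $|D|$ improves, multiplied by
$D_{t-2}/D_{t-1}$ under worsening over-allocation and by
$D_{t-1}/D_{t-2}$ under worsening under-allocation, clamped below at a
small floor.

Two numerical choices are worth spelling out:

* **Feasibility and budgets by maximum flow.** Before iterating, the
  demand is proved reachable by a max-flow computation on the class
  digraph (surpluses as sources, deficits as sinks, permitted
  conversions as unbounded inner edges, supply capped by each class's
  unfrozen cells). Infeasible demand fails fast with the size of the
  unservable deficit instead of spinning until the iteration cap. The
  per-edge flows double as class-to-class conversion *budgets*: sweeps
  only draw from budgeted transitions, so the allocation converges to
  the exact targets (tolerance 0 is attainable) instead of oscillating,
  and multi-step chains (A→B while B→C) resolve across sweeps.
* **No forbidden chained transitions.** A cell may only move to classes
  permitted from its *initial* class, not merely from its current one,
  so chains can never launder a forbidden conversion.

The packaged ecological-optimization scenario (`ecological_rules()`)
freezes water, forbids converting the high-value classes (forest, grass,
wet land) to cultivated or built-up land, and leaves cultivated and
built-up land unrestricted. Accuracy against a reference map is assessed
with `assess_accuracy()` (overall accuracy and kappa, with brute-force
marginal oracles in the test suite).

### 1.5 Corrected equivalent-factor ESV

`base_esv()` prices class areas with an 11-service × 8-class coefficient
table anchored at the unit equivalent value $E_a = \tfrac17\,p\,\bar g$
(one seventh of the value of the mean grain yield on one hectare of
average farmland). `revised_esv()` scales the base value by three
regional correction factors: grain-yield ratio $Q = G_A/G_N$; the
socio-economic development factor $D = P_w P_v$, where willingness to pay
$P_w$ is the ratio of logistic (Peal curve) development stages of the
Engel coefficient, $L(E) = 1/(1+e^{-(1/E-3)})$, and ability to pay
$P_v$ multiplies the per-capita-GDP and urbanization ratios; and
resource scarcity $S = \ln P_A / \ln P_N$ from population densities.
Engel coefficients are fractions in $(0,1)$ throughout — passing
percentages is an error, not a silent rescale. `esv_report()` derives
proportions, totals and growth rates; negative class values (built-up
land) are carried through the totals rather than truncated.

## 2. The synthetic-data module

The generator is a first-class part of the package: its defaults *are*
the study conditions for the end-to-end tests and the reproduction
script.

* **Landscape** (`generate_landscape()`): per-class smoothed Gaussian
  fields with iteratively calibrated offsets, assigned by argmax. This
  produces contiguous patches whose class shares match the requested
  fractions (calibration stops within 0.5% of each share) and whose
  spatial autocorrelation is verifiably above the random expectation
  (join-count statistic).
* **Default composition and trends** mirror a humid-province structure:
  dominant cultivated land (29% + 25%), substantial forest (22%),
  modest water (5%) and wet land (1%), growing built-up land (11%,
  trend +1.2%/yr) with slowly declining cultivated classes. The trends
  were chosen so that the implied horizon demand is *feasible* under the
  ecological rules — built-up growth must be coverable by the cultivated
  surplus, because nothing else may convert to built-up land. Stronger
  growth rates make the scenario provably infeasible and the CA refuses
  it; this interplay is deliberate and tested.
* **Driving factors** (`generate_driving_factors()`): 16 named layers —
  5 continuous socio-economic/terrain fields, 6 Euclidean distance maps
  to synthetic feature sets (roads, rivers, settlements, …), and 5
  multi-class soil/slope layers — the typical factor complement of
  land-use change studies.
* **Series** (`generate_area_series()`,
  `generate_socioeconomic_series()`): geometric class-area trends with
  small lognormal noise (±1% cap) renormalized to conserve total area,
  and region/nation socio-economic pairs with domain-valid Engel
  coefficients, densities and ratios.
* **Map evolution** (`evolve_landscape()`): changes an exact number of
  cells by rule-permitted transitions, never touching masked cells, and
  attaches a change ledger, which gives the test suite an exact oracle
  for transition-matrix estimation.

## 3. Problem sizes and runtime

Default problem sizes are our own choice, set for fast, deterministic
CI-scale runs: a $100\times100$ grid (10,000 cells), 5 survey years, a
2-step forecast horizon. A full `run_pipeline()` at these sizes takes
under ten seconds on one CPU. The components scale to larger grids — the
neighborhood pass is linear in cells, and allocation cost is dominated by
sweeps × candidate cells — but none of the shipped defaults assume it.

## 4. Reproducibility

A single seed fans out to fixed per-stage offsets, so every stage is
independently reproducible and the whole run is checksum-identical
across repetitions (`tools::md5sum` over the text artifacts written by
`run_pipeline(out_dir=)`). All outputs are plain text: ESRI ASCII grids
with a legend CSV sidecar for rasters (a deliberate choice — it is the
simplest interchange format every GIS reads, and round-trips integer
categorical data exactly), CSV for tables, YAML for configuration and
run metadata. `pipeline_config()` rejects unknown keys so typos cannot
silently corrupt a scenario.

## 5. Limitations

* The grids are plain lattices: no coordinate reference system,
  projection or reprojection support.
* GM(1,1) assumes equally spaced, positive series; unequal survey
  spacing must be handled upstream (interpolation or resampling).
* The ESV correction factors scale all services uniformly; no
  service-specific regional adjustment is attempted.
* The synthetic generator reproduces the *structure* of real landscapes
  (patchiness, shares, trends), not their geography; validation
  accuracies on synthetic runs are therefore optimistic relative to real
  rasters.
* The ANN is a single-hidden-layer network; with strongly nonlinear or
  interacting factors, its suitability surfaces will be smoother than
  those of ensemble learners.

## 6. A minimal run

```{r pipeline, eval = FALSE}
run <- run_pipeline(scenario_spec(seed = 1L), seed = 1L,
                    out_dir = "run_artifacts")
print(run)
```
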