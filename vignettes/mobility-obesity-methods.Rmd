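---
title: "Methods: mobility-derived diet and physical activity measures for neighborhood obesity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobility-derived measures for obesity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobesity)
```

## The problem

Neighborhood obesity prevalence is usually estimated from socioeconomic and
demographic covariates. Aggregated, anonymized mobile-phone location panels
offer a complementary signal: how often the residents of a census tract
actually visit fast-food restaurants, fitness and sports centers, and nature
parks. `mobesity` implements the full analysis chain for asking how much
such mobility-derived measures improve tract-level obesity estimation, and —
because the commercial visit panels and the joined health/census extracts
cannot be redistributed — pairs it with a synthetic-data generator whose
ground truth is known, so every stage can be tested for parameter recovery
rather than eyeballed.

## From censored visit panels to visit frequencies

Visit panels are POI-centric: each record says how many devices whose home
tract is $j$ visited POI $i$. Two privacy rules censor the counts: a
tract-POI pair with a single visitor is deleted, and counts of 2-4 are
recorded as 4. The derivation stage:

1. **Imputes** each recorded 4 by a draw from $\{2, 3, 4\}$ with
   $P(k) \propto k^{-\alpha}$, the power-law form typical of human travel
   behavior. The exponent is not identifiable from the censored data; the
   default $\alpha = 2$ sits in the middle of the range reported for human
   mobility (roughly 1.5-2.5) and is exposed as a parameter, with tests
   sweeping it ($\alpha = 0$ is the uniform limit). At $\alpha = 2$ the pmf
   is $(0.5902,\, 0.2623,\, 0.1475)$.
2. **Reverses** the panel to tract focus, summing counts per tract and POI
   category over *all* POIs, wherever located — residents visit places
   outside their own neighborhood and city.
3. **Divides** by the tract's resident device count $S_j$:
   $\mathrm{vf}_{jc} = \sum_i V_{ijc} / S_j$, yielding the three measures
   `fast_food_vf`, `fitness_vf`, `nature_park_vf`.

Tracts with no surviving records get frequency 0, not `NA`: under the data
model, the absence of recorded visits is informative. The device-count
denominator is treated as a single scalar per tract (the panel's
time-averaging, if any, happens upstream of this package). With imputation
disabled the derivation is a pure function; with it enabled, draws come from
one seeded stream in record-sorted order.

## The synthetic study

The generator emulates the three proprietary sources at once, with the
statistical features the analysis actually relies on:

* **Tracts** sit on a jittered grid (point support). Real tract polygons are
  not modeled because every operation downstream — k-NN weights, Moran's I,
  GWR, GRF — consumes only centroid distances. Coordinates are planar,
  km-like, with no projection handling.
* **Demographics** (24 variables mirroring the usual six groups) load on a
  latent, spatially smooth deprivation factor. The three education shares
  are exactly compositional (sum to 100), reproducing the near-singular
  design that makes VIF elimination necessary; the poverty-related
  variables are strongly mutually correlated by construction.
* **Visits** follow a gravity kernel: the expected count for a tract-POI
  pair is the tract's device count times $(1+d)^{-\gamma}$ in distance,
  scaled per category by a latent *behavior propensity*; counts are negative
  binomial (dispersion configurable) so the $\le 4$ censoring bites at a
  realistic rate. The marginal distribution of real panels is not public;
  this choice is a stand-in, not an inference about the data vendor.
* **The outcome** is a linear predictor on standardized covariates plus a
  simultaneous-autoregressive (SAR) error on row-standardized k-NN weights
  plus iid noise, affinely mapped to a prevalence-like percentage scale.
  The default `sar_rho = 0.7` reproduces the strongly positive spatial
  autocorrelation regime reported for real tract-level obesity (global
  Moran's I around 0.5-0.7 on k-NN weights). A `spatial_coef_amplitude`
  knob makes the first coefficient vary smoothly east-west, giving GWR and
  GRF something genuinely local to recover.
* **Coupling.** The same behavior propensity that drives visits can enter
  the outcome, with `behavior_share` fixing its share of outcome variance.
  This is the crucial dial for the experiment's logic: with
  `behavior_share = 0.15` (the default) the derived measures carry signal
  beyond the demographics, producing the "small but real improvement"
  regime; with 0 they are pure noise and information criteria should favor
  the baseline.
* A small fraction of tracts get populations below 50 or missing outcomes,
  so the exclusion rule (drop tracts with fewer than 50 residents or no
  recorded prevalence; a tract with exactly 50 residents stays) always has
  work to do.

Defaults were chosen once as the study conditions: `n_tracts = 900` (the
order of a large city's tract count), 60/40/25 POIs per category,
`gravity_decay = 1.5`, 200 devices per average tract, and the coefficient
signs follow the canonical epidemiological pattern (deprivation and
fast-food visits up, income and fitness visits down).

What passing tests on this generator do **not** show: robustness to real
polygon adjacency, temporal panel structure, survey measurement error in
the covariates, or the vendor's actual count distribution. They do show
that every estimator recovers what it claims to estimate when the data
satisfy its assumptions.

## Diagnostics

* **Spatial weights.** The weighting scheme behind published Moran's I
  values is typically unstated; the package defaults to k-nearest-neighbor
  (k = 8) binary weights, row-standardized — contiguity weights are
  impossible on centroid-only data. Distance ties break by tract order,
  so duplicated centroids are deterministic, not an error.
* **Moran's I** uses the double-sum formula with expectation $-1/(n-1)$.
  Because the inference method behind published "p < 0.001" statements is
  usually unspecified, both a seeded permutation p (999 permutations,
  two-sided by doubling the smaller one-sided rank p) and the
  normal-approximation p are reported.
* **Standardization** uses the sample standard deviation ($n-1$), matching
  mainstream statistical software.
* **VIF** is $1/(1-R^2_j)$ with an intercept in every auxiliary regression
  (harmless after centering, conventional otherwise); exact collinearity
  reports `Inf`. The cascade removes the single worst variable per round
  (ties: lexicographically first) until all VIFs fall below the typical
  cutoff of 5; `forced_removals` lets an analyst replay judgment-based
  multi-variable rounds deterministically. Termination is guaranteed since
  each round strictly reduces the dimension.

## The five estimators

All five share a fit/predict/`tidy()`/`glance()` contract.

* **OLS** (`stats::lm`): coefficients with t-based p-values and the
  conventional significance tiers, in-sample $R^2$, adjusted $R^2$, RMSE,
  Gaussian AIC.
* **GWR**: per-location weighted least squares with an *adaptive* bisquare
  kernel — the bandwidth is a neighbor count, not a distance, because
  tract densities vary hugely; the focal point counts among its own
  neighbors and receives bisquare weight 1. The effective number of
  parameters is the hat-matrix trace $\mathrm{tr}(S)$, and the corrected
  AIC is $2n\ln\hat\sigma + n\ln 2\pi + n\,(n+\mathrm{tr}(S))/(n-2-\mathrm{tr}(S))$
  with $\hat\sigma^2 = \mathrm{RSS}/n$. Bandwidth selection runs
  golden-section search inside a bracket found by a coarse scan over
  $[p+2, n]$ (a flat AICc tail cannot strand the search), with a dense-grid
  fallback and warning when the criterion is non-finite on the scan. A
  locally singular design falls back to a tiny ridge ($10^{-8}$) with a
  warning. RMSE is computed from the per-location fitted values — the
  local-ensemble reading of "model fit". With a uniform kernel and
  bandwidth $n$, GWR reproduces OLS exactly; this nesting is tested at
  $10^{-8}$.
* **RF** (`ranger`): seeded bootstrap, impurity importances normalized to
  sum to 1, out-of-bag $R^2$ for diagnostics.
* **GRF**: a global forest plus one local forest per location, trained on
  its `n_local_neighbors` nearest units (floor 20; blending weight 0.5 by
  default — the original formulation leaves both unspecified, so both are
  configurable and the degenerate corner `blend_weight = 1` provably equals
  the global forest). Out-of-sample points are served by the local forest of
  the nearest training location, retrained deterministically from
  per-location derived seeds. Local importances are retained per location
  for mapping spatially varying variable relevance.
* **DNN**: a fully connected ReLU network (one or two hidden layers), Adam,
  full-batch, early stopping on a 20% validation split, architecture chosen
  from the small grid {1, 2} layers × {16, 32, 64} units by validation MSE.
  It is written in base matrix algebra and is bit-deterministic for a given
  seed (dropout defaults to 0 for exactly this reason). Fitting refuses
  samples below 100 rows — with a 77-tract city the validation split cannot
  support model selection, mirroring how such models fail on small cities.

## The experiment

`compare_models()` runs each estimator on the **baseline** set (the
post-cascade demographic variables) and the **test** set (baseline plus the
three visit frequencies; the measures are standardized together with the
other covariates). Metrics follow the reporting convention for this kind of
study: statistical models (OLS, GWR) report in-sample $R^2$, adjusted
$R^2$, RMSE, and AIC; machine-learning models (RF, DNN, GRF) report
tenfold-cross-validated $R^2$ and RMSE, with $R^2$ computed on the pooled
out-of-fold predictions (stabler than averaging per-fold $R^2$ when a city
has only ~77 tracts; the alternative is a one-line change). Improvement
flags compare at three decimals and report ties as ties rather than wins.
A per-model failure — the network on a tiny city — becomes an annotated
report row, not an abort.

One subtlety the synthetic ground truth makes visible: when the VIF cascade
eliminates a variable that truly drives the outcome, the deprivation-
correlated visit measures partially absorb its signal, so they can improve
fit even when the generator couples behavior to the outcome not at all.
Pure-noise null checks therefore fix the baseline to retain every true
driver; with real data the analogous effect is one more reason derived
mobility measures and socioeconomic covariates appear mutually redundant.

`stepwise_regression()` starts from the three measures and adds
demographics by smallest entry p-value below 0.05, with a backward pass at
0.05 after each entry that may drop *any* current variable, measures
included, recording which entrant triggered the drop. The thresholds are
the most common convention (the criterion behind published stepwise tables
is rarely stated) and both are exposed; an information-criterion variant
would be a natural extension.

## Numerical choices and edge cases

* Seeds: one master seed; every stage derives its own 32-bit stream, so
  identical configurations are bit-identical end to end (tested on full
  pipeline reruns, byte-for-byte on the JSON artifacts).
* Degenerate inputs raise typed conditions: constant vectors for Moran's I
  or correlations, zero-sd columns for standardization, rank-deficient
  global designs for OLS, empty post-filter analyses.
* Problem sizes used by the test suite: oracle equivalences at 50-120
  points; parameter recovery at n = 2000 (OLS), 400 (GWR surface), 800
  (GRF split signal); the experiment-logic checks at the default n = 900
  over 10 seeds; end-to-end determinism on two full n = 900 runs.

## Known limitations

* Point-support geometry only; no contiguity weights, no polygon areas.
* The imputation exponent is a convention, not an estimate; conclusions
  that depend on the exact split of 2s, 3s and 4s should be checked across
  $\alpha$.
* GWR inference is descriptive (local coefficients, effective parameters);
  no local coefficient standard errors are reported.
* The DNN is deliberately small; it demonstrates the tabular-data regime
  where deep models match shallow ones, not state-of-the-art deep learning.
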