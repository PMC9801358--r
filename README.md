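# mobesity

Can aggregated, privacy-censored mobile-phone visit data improve
neighborhood-level obesity estimation beyond the socioeconomic and
demographic covariates epidemiologists already use? `mobesity` implements
the full analysis chain for that question at census-tract scale, for
spatial epidemiologists and health-geography analysts:

1. **Derive diet and physical activity measures** from a POI-centric visit
   panel censored for privacy (tract→POI counts of 1 deleted; counts 2–4
   recorded as 4). Censored counts are imputed from a power law on
   {2, 3, 4} with P(k) ∝ k<sup>−α</sup>, the panel is reversed to tract
   focus, and each tract's per-category total is divided by its resident
   device count:

   vf<sub>jc</sub> = Σ<sub>i</sub> V<sub>ijc</sub> / S<sub>j</sub>

   giving three measures per tract: fast-food, fitness-center, and
   nature-park visit frequency.
2. **Diagnose** the design: global Moran's *I* with permutation inference
   on k-nearest-neighbor weights, and iterative variance-inflation-factor
   (VIF) elimination of collinear demographics (cutoff 5).
3. **Compare five estimators** — OLS, geographically weighted regression
   (adaptive bisquare kernel, golden-section bandwidth on corrected AIC),
   random forest, a small feed-forward network, and geographical random
   forests (per-location forests blended with a global one) — on a
   *baseline* covariate set versus a *test* set that adds the three
   measures. Statistical models report in-sample R², adjusted R², RMSE,
   AIC; machine-learning models report tenfold-cross-validated R² and RMSE.
4. **Probe redundancy** with stepwise regression starting from the three
   measures, recording which entering demographic renders a measure
   insignificant.

Because the real inputs (commercial visit panels joined to public health
and census tables) cannot be redistributed, the package ships a
first-class synthetic-data generator with known ground truth: collinear,
partly compositional demographics driven by a latent deprivation factor; a
gravity-model visit process with negative-binomial counts and the privacy
censoring above; and a spatially autocorrelated outcome
(simultaneous-autoregressive error) optionally coupled to the latent
visit behavior. Every estimator is tested for recovering that ground truth.

## Worked example

```r
library(mobesity)

cfg   <- sim_config(n_tracts = 300, seed = 42)
study <- sim_study(cfg)                 # tracts, POIs, censored visits, measures
tracts <- filter_tracts(study$tracts)
#> 14 census tract(s) (4.7%) excluded (population < 50 or missing prevalence); 286 retained

head(study$measures, 3)
#> # A tibble: 3 × 4
#>   tract_id fast_food_vf fitness_vf nature_park_vf
#>   <chr>           <dbl>      <dbl>          <dbl>
#> 1 t00001         0.0943      0.104         0.0377
#> 2 t00002         0.247       0.617         0.279
#> 3 t00003         0.213       0.580         0.0517

w <- knn_weights(tracts, k = 8)
morans_i(tracts$obesity_prevalence, w, n_permutations = 999, seed = 1)
#> Global Moran's I: 0.4265 (expected -0.0035 under the null)
#>   permutation p (two-sided, 999 perms): 0.002; normal-approx p: 5.228e-52

comp <- compare_models(tracts, study$measures, models = c("ols", "rf"),
                       seed = 1, specs = list(rf = list(n_trees = 200)))
comp
#> Baseline vs test comparison (n = 286, 10-fold CV for ML models)
#>  model      set     r2  rmse adjusted_r2  aic    source note
#>    ols baseline 0.8943 2.255      0.8867 1319 in_sample <NA>
#>    ols     test 0.9030 2.160      0.8949 1300 in_sample <NA>
#>     rf baseline 0.8437 2.742          NA   NA        cv <NA>
#>     rf     test 0.8642 2.556          NA   NA        cv <NA>
```

The visit frequencies are per-device rates (e.g. 0.25 ≈ one recorded
fast-food visit per four resident devices). Moran's *I* of 0.43 with
permutation p = 0.002 confirms the outcome is spatially clustered, which
is why the spatially explicit models are in the lineup. In the comparison,
the test rows beat the baseline rows on every metric (higher R², lower
RMSE and AIC): under the default generator, the derived measures carry a
modest signal beyond the demographics — the regime the method is designed
to detect. `tidy(comp)` adds per-metric improvement flags with ties
reported as ties; `autoplot(comp)` draws the comparison.

The whole chain — including VIF elimination, correlations, the five-model
report, and the stepwise trace — runs as one pipeline with on-disk,
resumable artifacts:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
# or: Rscript scripts/pipeline.R run-all --out run1 --seed 1
```

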