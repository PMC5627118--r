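# monarchthreats

Threat attribution for the eastern migratory monarch butterfly
(*Danaus plexippus*). The eastern population is censused each December as
the area (hectares) of high-elevation oyamel fir forest its overwintering
colonies occupy in central Mexico; that annual index has declined sharply
over two decades while dozens of candidate pressures — herbicide-driven
milkweed loss, overwinter forest loss, insecticides, parasitism, breeding
and overwintering climate — changed alongside it. With ~22 annual
observations and ~76 collinear covariates, ordinary regression cannot
separate those pressures. `monarchthreats` implements a multi-stage
attribution pipeline built for exactly this data shape, driven by a
synthetic-data generator that reproduces its statistical structure, so
every stage can be validated against known truth.

The package is written for quantitative ecologists and biostatisticians
working with short, wide environmental time series; everything takes a
data frame and returns a tibble, models come with broom-style `tidy()` /
`glance()` methods and `autoplot()` displays.

## The methods

1. **Missing-data interpolation (DINEOF).** Missing covariate cells are
   filled by iterative truncated singular value decomposition: completed
   matrix → rank-*k* SVD truncation → overwrite the missing cells →
   repeat. A random subset of observed cells is withheld and the number of
   EOF modes *k* is chosen to minimise their reconstruction RMSE
   (`dineof_impute()`).
2. **Y-aware variable reduction (PLS1).** NIPALS partial least squares
   with a single response extracts latent components maximising covariance
   between the covariate block **X** and the log population index
   (`fit_pls1()`). Model quality is judged by the fitted R², and by
   leave-one-out cross-validation: PRESS = Σᵢ (yᵢ − ŷᵢ/ᵢ)² and
   Q² = 1 − PRESS/TSS (`pls_loo()`). Variables are screened by
   correlation loading (|loading| ≥ 0.15, top 10 per component;
   `select_by_loadings()`) and pruned so no retained pair has |r| > 0.6,
   preferring the north-central breeding region's variant of redundant
   covariates (`correlation_filter()`).
3. **Best-subset Gompertz time-series regression.** The log index follows
   N_t = α₀ + β′X_t + ε_t, ε_t ~ N(0, σ²), with the previous year's log
   abundance available as an ordinary covariate (density dependence).
   Every subset of the reduced variable set (e.g. all C(11,4) = 330
   subsets of size 4) is fitted by Gaussian maximum likelihood and ranked
   by BIC = −2 logLik + k log n with k = covariates + 2
   (`best_subset_gompertz()`). BIC weights ω_i ∝ exp(−Δ_i/2) give a
   confidence set (Δ ≤ 10), per-variable importance (summed weights) and
   shrinkage model-averaged coefficients (zeros where a variable is
   absent). Residual ACF diagnostics and an exact-ML AR(1)-error
   alternative (`fit_ar1_gls()`) guard against leftover temporal
   structure.
4. **Structural path model.** The causal chain
   log(population) ← log(milkweed resource) ← log(cumulative glyphosate)
   is fitted as a recursive three-variable path model; the single omitted
   direct path gives a χ² test on 1 df, with RMSEA and CFI fit indices
   (`fit_path_model()`, `fit_indices()`).

The generator (`simulate_monarch_data()`) emulates the study conditions:
22 years, a near-collinear monotone trend block (cumulative pesticide and
land-use series), regionally correlated stochastic climate blocks, an
infection-proportion covariate, historically patterned missingness, and a
milkweed series causally downstream of the herbicide driver. Degree-day
covariate engineering is included: growing degree days between 11.5 °C
and a 36 °C cap (`compute_gdd()`), lethal degree days above 38 °C
(`compute_ldd()`), and annualization of multi-year forest-loss totals
(`annualize_periods()`).

## Worked example

```r
library(monarchthreats)

sim <- simulate_monarch_data(simulation_config(seed = 42))
sim
#> <monarch_sim> 22 years x 76 covariates; 99 masked cells

result <- run_pipeline(data = sim)
result
#> <monarch_pipeline> stages:
#>   simulate 0.00s  (provided)
#>   impute   0.73s  (modes=4)
#>   pls      0.11s  (6 variables retained)
#>   select   0.03s  (15 models)
#>   sem      0.00s
#> reduced set: 6 variables; 15 candidate models
```

Four EOF modes were enough to reconstruct the 99 masked cells; the
two-component PLS screen kept 6 covariates after correlation pruning, and
the exhaustive size-4 enumeration over them produced 15 candidate models.

```r
glance(result$pls)
#> # A tibble: 1 x 3
#>   n_components fitted_r2 explained_y_pct_total
#> 1            2     0.717                  71.7
result$pls_cv
#> # A tibble: 1 x 3
#>   press    q2   tss
#> 1  8.26 0.255  11.1
```

Two components fit 71.7% of the response variance in-sample; the
leave-one-out Q² of 0.26 is much lower, as expected for 22 observations —
the gap is the honest price of the short series.

```r
variable_importance(result$model_set)
#> # A tibble: 6 x 2
#>   variable               importance
#> 1 clim_north_central_01       1.000
#> 2 trend_north_central_07      1.000
#> 3 clim_north_central_04       0.927
#> ...
```

The selection machinery puts full importance on a north-central trend
covariate and the two active climate covariates. The generator's truth
routed the trend effect through `trend_north_central_01`; the pipeline
retained `trend_north_central_07` from that near-collinear block (within-
block r > 0.99) — the collinearity regime in which *which* trend proxy is
named is not identifiable, only that the trend block matters.

```r
result$path_fit
#> <monarch_pathfit> n = 22; gamma = -0.566, delta = 0.76
#> chi2(1) = 1.63, p = 0.202; RMSEA = 0.173, CFI = 0.9746
```

The path model's omitted direct herbicide-to-population link is not
rejected (p = 0.20): consistent with the generating mechanism, where the
herbicide effect acts entirely through the milkweed resource.

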