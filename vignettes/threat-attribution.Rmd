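---
title: "Attributing threats to the monarch overwintering population: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing threats to the monarch overwintering population: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monarchthreats)
```

`monarchthreats` implements a four-stage attribution analysis for the
annual overwintering index of the eastern migratory monarch butterfly —
the December census of hectares of oyamel fir forest occupied by
colonies in central Mexico, used (on the natural-log scale) as a proxy
for total population size. The statistical problem is extreme by design:
roughly three times as many candidate covariates as annual observations,
strong within-block collinearity, and historically patterned missingness.
This vignette explains each stage's model and assumptions, the tunable
parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the methodology leaves room.

## The synthetic-data generator

`simulate_monarch_data()` draws a year-by-variable table whose structure
matches the assembled observational record the pipeline targets:

* **22 annual observations** (1993–2014) of a log-scale response
  (`log_area`, log hectares).
* **A monotone "trend" block** (40 covariates by default): logistic
  adoption curves — the canonical shape of technology uptake such as
  herbicide-resistant crop adoption — accumulated over time, with
  region-shared timing and small per-variable jitter. Accumulation makes
  the block near-collinear both within and across regions (sample
  correlations above 0.99), reproducing the regime in which cumulative
  pesticide, land-conversion and forest-loss series are statistically
  interchangeable. This is the regime the reduction machinery must
  survive, so it is the default, not an option.
* **A stochastic climate block** (34 covariates): AR(1) series (lag
  correlation 0.3) sharing a regional factor. The within-block
  correlation defaults to 0.45 — a moderate shared-variance level chosen
  to reflect regional mean climate series that co-vary without being
  redundant; it is deliberately below the 0.6 pruning threshold so that
  pruning is driven by genuine redundancy plus sampling noise rather
  than being guaranteed in either direction.
* **An infection-proportion covariate** (`prop_inf`), a bounded AR(1)
  series on the logit scale, and **the previous year's log abundance**
  (`apva_1yr`) as an ordinary candidate covariate.
* **Missingness** per covariate follows a configurable count map whose
  default mirrors the historical record: 7 missing years for the
  infection series, 2 for pesticide-style series, 1 for the lagged
  response and for a third of the climate series. Masking is uniform at
  random within a column by default; a `"tail"` mode masks the final
  years instead, mimicking series whose collection simply stopped, which
  is how most real gaps arose.

The response follows the Gompertz-type regression
$N_t = \alpha_0 + \varphi N_{t-1} + \sum_j \beta_j z_{jt} + \varepsilon_t$
with standardized covariates $z$ and $\varepsilon_t \sim N(0, \sigma^2)$.
Defaults: $\alpha_0 = 1.5$ (log ha), $\sigma = 0.3$, $\varphi = 0$, and
true standardized coefficients $(-0.506, -0.131, -0.139)$ on one
north-central trend covariate and two north-central climate covariates —
the effect-size pattern of a dominant slowly evolving pressure plus two
weaker climate effects. $\varphi$ defaults to zero because a monotone
trend covariate absorbs the long-term decline, which in data of this
shape empirically obviates an explicit autoregressive term; it remains a
config field for studying density-dependent variants.

**The milkweed chain.** A log milkweed-resource series is generated
downstream of the herbicide driver,
$m_t = 5 + \gamma_{mw} z_{gly,t} + e_t$, and — this matters — when the
driver carries a true coefficient its effect on the response is routed
*through* $m_t$ rather than added directly. The simulated system
therefore genuinely has the recursive structure
glyphosate → milkweed → population with no direct link, which is the
null hypothesis the path-model stage tests; the driver's total effect on
the response still equals its stated coefficient. Without this routing, a
generator that feeds the driver into the response directly would make the
path model's one testable restriction false by construction.

What the generator does **not** emulate: observation error in the index
(the real index is itself a state-space estimate), lagged pesticide
effects, spatial structure within regions, non-Gaussian innovations, and
trend–climate interactions. Passing recovery tests on these simulations
therefore show that the machinery is correct and calibrated for the
assumed data-generating shape — not that the real system satisfies that
shape.

## Covariate engineering

Growing degree days use the capped simple-average method: daily
contribution $\max(0, (\min(t_{max}, 36) + t_{min})/2 - 11.5)$ °C·day,
with 11.5 °C the monarch development base and 36 °C the upper
development threshold; the simple average (not a sine interpolation) is
used because the regional series this emulates are defined from daily
maxima and minima alone. Negative daily values are floored at zero — the
standard degree-day convention, which keeps accumulation monotone in
both temperatures and additive over windows. Lethal degree days count
$t_{max} - 37$ on days with $t_{max} \ge 38$ °C. Regional values average
the per-site sums with equal weight; nothing in the source methodology
specifies site weighting, and equal weights are the only choice that
does not invent site metadata. Multi-year forest-loss totals are
annualized by even division across the period's years (mass-conserving
by construction), with zero loss assumed before the first surveyed
period.

## Stage 1: DINEOF imputation

`dineof_impute()` fills missing covariate cells by iterative truncated
SVD. Cells start at their column means; each iteration standardizes the
completed matrix, truncates to rank $k$, and overwrites the missing (and
withheld) cells with the reconstruction. A withheld fraction
(`cv_fraction`, default 0.05) of observed cells serves as reference
values; the rank minimising their reconstruction RMSE (reported in
standardized units so columns with different physical units are
comparable) is selected, and the matrix is refit at that rank with all
observed cells participating. Observed cells are restored exactly in the
output, and the imputation is run on the covariate matrix only — the
response series is complete by construction.

Numerical choices worth knowing:

* **Centring and scaling are re-estimated every iteration** from the
  current completion, rather than fixed from the observed cells. Fixed
  constants subtly break exact low-rank structure: a rank-1 matrix whose
  complete columns all standardize to the same direction becomes
  unidentifiable at the selected rank, and the masked cell inherits its
  initialisation. Re-estimation keeps truly low-rank inputs low-rank on
  the working scale; the observed-cell means still provide the
  initial guesses.
* **Convergence** is declared when the RMS change of the re-estimated
  cells falls below `tol` times their magnitude. The default
  `tol = 1e-8` is deliberately tight: the iteration is a fixed-point
  contraction whose final error is of order `tol / (1 − ρ)` with ρ the
  leverage of the filled cells, so a looser tolerance (e.g. 1e-6) leaves
  errors orders of magnitude above machine precision on high-leverage
  cells.
* **The rank scan stops early** (`patience = 3`) once three consecutive
  ranks fail to improve the withheld-cell RMSE. Ranks beyond a clear
  minimum only overfit the reconstruction and, on 22-row matrices, often
  cycle without converging; `patience = Inf` restores the full scan. A
  warning is raised only when the refit at the *selected* rank hits
  `max_iter` (default 500); per-rank convergence flags are always in the
  report.
* A single global mode count is used for the whole matrix (standard EOF
  practice), and any column with fewer than two observed values is
  rejected rather than guessed at.

## Stage 2: PLS screening

`fit_pls1()` implements NIPALS PLS1 on standardized predictors and (by
default) a standardized response: weight $w \propto X'y$, score
$t = Xw$, loadings $p = X't/t't$, $q = y't/t't$, deflation
$X \leftarrow X - tp'$, $y \leftarrow y - tq$. Two components are the
default, matching the screening depth appropriate for a trend block plus
a climate block; Q²-guided component choice can be layered on by the
user via `pls_loo()`. Standardization uses the n−1 sample sd and is
re-estimated inside every cross-validation fold — leaking full-sample
centring constants into leave-one-out folds inflates Q² and is the
classic chemometrics mistake the fold-internal re-estimation avoids.

Variable selection uses **correlation loadings** — the correlation of
each original (undeflated) covariate with each score vector — because
that is the quantity with a direct "largest correlation" reading; the
NIPALS x-loadings $p$ are also reported for completeness. The threshold
rule (|loading| ≥ 0.15) applies first and the per-component cap (top 10)
second. Correlation pruning then groups candidates by single-linkage on
|r| > 0.6 and keeps one representative per group, preferring the
north-central region (where the bulk of breeding production occurs),
then the larger absolute loading, then the lexicographically first name
— three tie-breaks that make the reduction fully deterministic.

The response enters as the natural-log index, consistent with the
Gompertz stage; a `scale_y = FALSE` flag allows an unstandardized
response. Whether the 2-component explained-variance split refers to the
response space is taken as given: the package defines per-component
explained variance as $100 \, q_c^2 \, t_c't_c / \mathrm{TSS}$, which
sums to the fitted R² — a response-space decomposition.

## Stage 3: best-subset Gompertz regression with BIC weights

Every subset of the reduced variable set is fitted by least squares
(equivalently Gaussian ML) with standardized covariates, so coefficients
are comparable across covariates with different units. The enumeration
default is *exactly* size 4 — with 11 reduced variables, C(11,4) = 330
models — with a `min_size`/`exact = FALSE` mode for "all sizes up to 4";
both readings of "limited to ≤ 4 covariates" are defensible and both are
implemented, with neither hard-coded into downstream logic.

The likelihood uses the ML variance $\hat\sigma^2 = RSS/n$, giving
$\log L = -(n/2)(\log(2\pi\hat\sigma^2) + 1)$, and
$BIC = -2\log L + k\log n$ with $k$ = covariates + 2: the intercept and
the residual variance both count. This parameter-count convention is the
one under which published model tables of this analysis family are
internally consistent at n = 22, and the package's own tables recompute
exactly under it (a property the test suite asserts to 1e−12).

Weights, importance and averaging follow the standard
multimodel-inference toolkit: $\Delta_i = BIC_i - \min BIC$,
$\omega_i = e^{-\Delta_i/2} / \sum_r e^{-\Delta_r/2}$, importance =
summed weights of models containing the variable, and model-averaged
coefficients computed over the **full enumerated set with zeros where a
variable is absent**. Full-set averaging is the default because it is
what produces shrinkage toward zero in proportion to importance; a
confidence-set-only averaging mode (weights renormalised over Δ ≤ 10) is
exposed for users who want conditional averages. Rank-deficient subsets
are excluded from ranking — under the Gaussian ML convention their BIC
is undefined — rather than patched with a pseudo-inverse.

Residual diagnostics: `residual_acf()` reports the sample ACF with
±1.96/√n bounds, and `fit_ar1_gls()` refits any subset under AR(1)
errors by exact stationary ML (first observation scaled by
√(1−φ²), later ones quasi-differenced), profiling φ over a grid with
local refinement. At φ = 0 its likelihood equals the white-noise fit's,
and its BIC carries one extra parameter, so the two error models are
directly comparable.

## Stage 4: the structural path model

The recursive system

$$\log(\text{milkweed}) = \gamma \cdot \log(\text{cumulative glyphosate}), \qquad
\log(\text{population}) = \delta \cdot \log(\text{milkweed})$$

is a directed acyclic path model with uncorrelated errors, so its ML
estimates are the per-equation least-squares slopes and the standardized
$\hat\gamma$, $\hat\delta$ are plain correlations. The model frees 5 of
the 6 covariance moments of the three observed variables; the single
restriction — no direct glyphosate → population path — gives
$\chi^2 = (n-1) F_{ML}$ on 1 df, with
$F_{ML} = \log|\Sigma(\hat\theta)| + \mathrm{tr}(S\Sigma^{-1}(\hat\theta)) - \log|S| - 3$.
The (n−1) multiplier is the Wishart convention; an `"n"` switch exists,
and at the effect sizes this model serves the choice cannot move any
index at two decimals. When the sample moments are numerically singular
(the noiseless limit) the equivalent partial-correlation form
$-\,(n-1)\log(1 - r_{xy\cdot m}^2)$ is used, with a zero-residual guard
so that exact recursive data yield $\chi^2 = 0$ rather than 0/0.

Fit indices follow the conventional definitions — RMSEA
$= \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$ and CFI against the
independence baseline (all covariances zero, variances free, 3 df for
three variables). Both saturate (RMSEA = 0, CFI = 1) whenever χ² ≤ df.
Intercepts are excluded: the fit is covariance-structure-only on
standardized variables, matching the standardized coefficients reported.
One caveat is surfaced deliberately: a standardized simple-regression
slope γ and its equation R² satisfy R² = γ², so a report combining a
small |γ| with a large R² must involve an unstandardized or per-annum
slope; `fit_path_model()` therefore reports both the standardized and
the raw-scale slopes, and `simulate_path_data()` parameterises truth on
the raw scale.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages in order, each consuming only the
previous stage's artifacts, and writes plain-CSV artifacts plus a
manifest of stage timings and MD5 digests when an output directory is
given. A single root seed is split deterministically into per-stage
seeds so any stage can be reproduced in isolation; identical
configuration and seed give byte-identical artifacts.

The test suite exercises the calibration and recovery properties at
sizes chosen to keep the full suite around two minutes on one core while
leaving no property under-powered: 200 replicates at n = 22 for
confidence-set recovery (561 fitted subsets per replicate), 200
replicates at n = 200 for coefficient recovery, 200 replicates at
n = 1000 for the path-model null calibration, and 60–200 replicates for
the smaller recovery checks. These sizes are the package's choice of
test conditions, stated here so they can be scaled up by anyone wanting
tighter Monte-Carlo error.

## Known limitations

* The DINEOF stage assumes missingness unrelated to the missing values
  themselves; historically gappy series whose gaps track the covariate's
  own level would bias the reconstruction.
* PLS screening with 22 observations is a screening device, not an
  inference engine: Q² will sit far below the fitted R², and the
  selected variable list inherits sampling noise (the correlation
  pruning's determinism is conditional on the data, not on replication).
* Within a near-collinear trend block, *which* proxy is selected is not
  identifiable — only that the block matters. Interpretation should be
  at the block level.
* The path model is exactly three variables; it is not a general SEM
  (no latent variables, groups, or missing-data FIML), and its causal
  reading rests entirely on the assumed ordering.
* The AR(1) profile likelihood assumes stationarity (|φ| < 1) and a
  single lag; longer memory shows up only via the ACF diagnostics.
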