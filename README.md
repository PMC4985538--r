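# carbma

Bayesian model averaging for spatial Poisson models of air-pollution
health effects.

## What this package is for

Small-area studies of long-term pollution exposure regress areal disease
counts on an exposure surface and deprivation confounders with a Poisson
log-linear model.  The estimated effects are small, and they move with
three modelling choices that are usually fixed silently:

1. **which exposure surface** is used (raw dispersion-model output, or a
   measurement-calibrated "fusion" surface),
2. **which deprivation covariate** controls confounding (a composite
   index, or one of its domains), and
3. **how residual spatial autocorrelation** is handled (ignored; globally
   smooth CAR random effects; or orthogonal smoothing).

`carbma` fits the whole grid of such models — by default 2 exposures ×
7 deprivation choices × 3 spatial structures = 42 models — and combines
the exposure effect across them with Bayesian model averaging, so the
final interval carries the model uncertainty.  It is aimed at
biostatisticians and spatial epidemiologists who want the sensitivity
analysis, and its software plumbing, as tested and reproducible code.

## The models

Every model shares the core

```
Y_i | E_i, R_i ~ Poisson(E_i R_i),   log R_i = z_i' beta + phi_i,   beta ~ N(m, V)
```

with `z_i = (1, x_i, u_i)` (intercept, exposure in ug/m^3, deprivation),
so `beta_2` is always the exposure effect, reported as a relative risk
`exp(5 * beta_2)` per 5 ug/m^3.  The three spatial structures are

* **GLM** — `phi = 0` (no spatial structure, no overdispersion);
* **Leroux CAR** — `phi` has joint precision
  `(1/tau^2) [rho (diag(W1) - W) + (1 - rho) I]` over the binary
  adjacency `W`, interpolating between independence (`rho = 0`) and the
  intrinsic CAR (`rho = 1`);
* **Orthogonal smoothing** — `phi = M delta`, `M` the leading positive
  eigenvectors of `P' W P'` with `P' = I - Z (Z'Z)^-1 Z'`, and
  `delta ~ N(0, tau^2 (M' (diag(W1) - W) M)^-1)`; the smooth term is
  orthogonal to the covariates by construction, removing spatial
  confounding.

Fitting is adaptive Metropolis-within-Gibbs (C++ kernels), retaining
per-draw log-likelihood and log-prior.  Model weights come from the
Monte-Carlo marginal-likelihood average
`f(Y|M_k) ≈ (1/J) Σ_j f(Y|θ_j) f(θ_j|M_k)` under a uniform model prior,
and the combined effect uses the mixture moments of `beta_2` across
models.  DIC with effective parameters, RMSE of fitted counts, a Pearson
overdispersion statistic and a Moran's I permutation test are included,
as is a synthetic-data generator that produces complete studies (graph,
populations, expected counts, correlated deprivation domains, paired
exposure surfaces, CAR-structured counts) with known ground truth.  The
methods vignette (`vignettes/spatial-bma.Rmd`) documents every formula,
default and design decision.

## Worked example

Generate a 400-zone synthetic study, check the pre-model diagnostics,
fit a 2 × 2 × 3 grid and average it:

```r
library(carbma)

study <- generate_study(default_scenario(n = 400, rows = 20, cols = 20), seed = 1)
study
#> synthetic_study: 400 zones; mean SMR 1.046

Z <- build_design(study$zones$exposure_modelled, study$zones$income)
overdispersion_statistic(study$zones$Y, study$zones$E, Z)
#> [1] 3.79   # Poisson GLM residuals are strongly overdispersed ...
morans_i_permutation_test(glm_pearson_residuals(study$zones$Y, study$zones$E, Z),
                          study$graph, n_perm = 999, seed = 2)[c("statistic", "p_value")]
#> $statistic 0.305 ; $p_value 0.001   # ... and spatially autocorrelated

cfg <- study_config(
  exposures = c("modelled", "fusion"),
  deprivations = c("income", "simd"),
  mcmc = mcmc_config(chains = 3, iterations = 10000, burnin = 5000, thin = 5, seed = 1),
  q = 50, seed = 10, psrf_threshold = 1.1, on_nonconverged = "exclude")
res <- run_study(study, cfg)
res
#> study_result: 12 models; 0 intervals exclude RR = 1
#> Bayesian model averaging over 12 models
#>   combined RR per increment: 1.021 (0.987, 1.057)
#>   P(RR > 1) = 0.876
#>   top model weights:
#>     modelled/income/leroux        75.77%
#>     modelled/simd/leroux          22.50%
#>     fusion/income/leroux           1.32%
#>     fusion/simd/leroux             0.41%
#>     modelled/simd/os               0.00%
```

The study was generated with a true RR of 1.011 per 5 ug/m^3 driven by
the *modelled* exposure with *income* as the true confounder — and the
averaging concentrates 76% of the weight on exactly that model, with the
combined RR of 1.021 (0.987, 1.057) covering the truth.  The diagnostics
read the same way they would in a real analysis: overdispersion ~3.8 and
Moran's I of 0.305 (p = 0.001) on the GLM residuals are the evidence
that the non-spatial model is inadequate, and the fit table confirms it
(the Leroux models lead on DIC):

```r
head(res$fit_table[order(res$fit_table$dic), ], 3)
#>    exposure deprivation structure      dic      p_d     rmse
#> 2  modelled      income    leroux 2571.733 212.3912 3.339343
#> 5  modelled        simd    leroux 2571.782 214.1031 3.305830
#> 11   fusion        simd    leroux 2572.721 214.0660 3.316585
```

`write_study_tables(res, "out/")` emits the relative-risk table, the
DIC/p_D/RMSE table, the BMA report (CSV + JSON) and a run log.  A thin
command-line wrapper with `simulate` / `grid` / `report` subcommands is
in `inst/cli/carbma.R`.

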