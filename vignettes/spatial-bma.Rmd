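---
title: "Spatial Poisson models and model-averaged pollution-health effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial Poisson models and model-averaged pollution-health effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Small-area ("spatial ecological") studies of air pollution and health
regress areal disease counts on an exposure surface and confounders.  For
each of $n$ zones we observe deaths $Y_i$ and an expected count $E_i$ from
indirect standardisation, $E_i = \sum_r N_{ir}\gamma_r$, where $N_{ir}$ is
the zone population in age--sex stratum $r$ and $\gamma_r$ the region-wide
stratum mortality rate.  The quantity of interest is the effect of the
exposure (here NO$_2$, in $\mu$g\,m$^{-3}$) on disease risk, reported as a
relative risk per 5 $\mu$g\,m$^{-3}$.

Estimated effects of this kind are small, and they move with three
modelling choices that are usually fixed silently: which version of the
exposure surface is used (raw dispersion-model output versus a
measurement-calibrated "fusion" surface), which deprivation covariate
controls confounding (a composite index or one of its domains), and how
residual spatial autocorrelation is handled.  `carbma` fits the full grid
of such models and combines the exposure effect across them by Bayesian
model averaging, so that model uncertainty is carried into the final
interval instead of being discarded.

# The three model structures

All models share the Poisson log-linear core

$$Y_i \mid E_i, R_i \sim \text{Poisson}(E_i R_i), \qquad
  \log R_i = z_i^\top\beta + \phi_i, \qquad \beta \sim N(m, V),$$

with $z_i^\top = (1, x_i, u_i)$ (intercept, exposure, deprivation), so
$\beta_2$ is always the exposure effect.  They differ in $\phi$:

* **GLM** (`fit_glm`): $\phi_i = 0$.  Ignores residual autocorrelation and
  overdispersion; included as the baseline.
* **Leroux CAR** (`fit_leroux`): $\phi$ has the proper conditional
  autoregressive prior with joint precision
  $Q = \tau^{-2}[\rho(\mathrm{diag}(W\mathbf 1) - W) + (1-\rho)I]$ over the
  binary adjacency $W$.  Its full conditionals are
  $\phi_i \mid \phi_{-i} \sim N\!\big(\tfrac{\rho\sum_j w_{ij}\phi_j}
  {\rho\sum_j w_{ij}+1-\rho},\ \tfrac{\tau^2}{\rho\sum_j w_{ij}+1-\rho}\big)$;
  $\rho = 0$ is independence and $\rho = 1$ the intrinsic CAR.
* **Orthogonal smoothing** (`fit_orthogonal`): $\phi = M\delta$, where the
  columns of $M$ are the $q$ eigenvectors of $P' W P'$
  ($P' = I - Z(Z^\top Z)^{-1}Z^\top$) with the largest positive
  eigenvalues, and $\delta \sim N(0, \tau^2 Q_s^{-1})$ with
  $Q_s = M^\top(\mathrm{diag}(W\mathbf 1) - W)M$.  Because every basis
  column is orthogonal to $Z$, the smooth term cannot be collinear with
  the exposure (no spatial confounding).  $q$ trades smoothing dimension
  against parsimony; the default is 50.

Islands (zones with no neighbours) are rejected at graph validation: the
CAR conditionals divide by $\rho\sum_j w_{ij} + 1 - \rho$, which is safe,
but an island silently changes what the prior means, so the package fails
loudly instead of redefining it.

# Priors and sampling

Defaults are the weakly informative choices common in disease mapping:
$m = 0$, $V = 10^5 I$, $\tau^2 \sim$ inverse-gamma$(1, 0.01)$,
$\rho \sim U(0,1)$.  All are overridable through `prior_spec()`.

Sampling is adaptive Metropolis-within-Gibbs, implemented in C++:

* $\beta$: joint random-walk proposals scaled by the maximum-likelihood
  standard errors, with a global scale adapted toward roughly 40%
  acceptance **during burn-in only**, so retained draws come from a fixed
  kernel.
* $\phi_i$: single-site random-walk Metropolis using the CAR full
  conditional as prior; $\phi$ is mean-centred every iteration so the
  intercept is identified (the smooth term in the orthogonal model is
  centred by construction, since $M^\top\mathbf 1 = 0$).
* $\tau^2$: conjugate inverse-gamma Gibbs update with shape $a + n/2$
  (Leroux) or $a + q/2$ (orthogonal).
* $\rho$: random-walk on the logit scale with the Jacobian correction, so
  the uniform$(0,1)$ prior is respected.  The determinant term uses the
  eigenvalues $\lambda_i$ of $\mathrm{diag}(W\mathbf 1) - W$, computed
  once: $\log\det Q(\rho) = \sum_i \log(\rho\lambda_i + 1 - \rho)$.

Initial values are deterministic ($\beta$ at the IRLS maximum-likelihood
fit, $\phi = 0$, $\rho = 0.5$, $\tau^2 = 0.01$), and chain $c$ of a fit
seeds the R RNG with `seed + c - 1`, so every fit is exactly
reproducible.  The reference protocol is 5 chains $\times$ 120{,}000
iterations, 20{,}000 burn-in, thinned by 10 (50{,}000 retained draws);
`(iterations - burnin)` must divide by `thin`, enforced at configuration.

Every retained draw stores its log-likelihood and its **full** log-prior
(all of $\beta$, $\phi$ or $\delta$, $\tau^2$, $\rho$, with normalising
constants).  This matters because the model weights below are built from
likelihood-times-prior values, where constants do not cancel.

# Model averaging

With $K$ candidate models and a uniform prior over them, the posterior
model probabilities are

$$f(M_k \mid Y) = \frac{f(Y \mid M_k)}{\sum_l f(Y \mid M_l)}, \qquad
  f(Y \mid M_k) \approx \frac{1}{J}\sum_{j=1}^J
  f(Y \mid \theta_k^{(j)}) f(\theta_k^{(j)} \mid M_k),$$

the average running over the retained posterior draws.  Evaluated with
posterior samples, this Monte-Carlo average converges to the posterior
expectation of likelihood-times-prior rather than to the prior-predictive
integral it is written to approximate.  `carbma` implements it exactly as
written (it is the estimator the averaging procedure is defined with, and
the package's tests verify it against quadrature on a conjugate toy
*for that estimand*), and exposes a clearly labelled harmonic-mean
alternative (`log_marginal_likelihood(..., method = "harmonic")`) for
comparison rather than silently "correcting" it.  In practice the
estimator behaves like an aggressive goodness-of-fit weight: it
concentrates mass on the best-fitting one or two models.

The combined effect uses the mixture moments
$E(\beta_2 \mid Y) = \sum_k \hat\beta_{2k} w_k$ and
$\mathrm{Var}(\beta_2 \mid Y) = \sum_k [\mathrm{Var}(\beta_2 \mid M_k, Y) +
\hat\beta_{2k}^2] w_k - E(\beta_2 \mid Y)^2$, with $\hat\beta_{2k}$ the
per-model posterior median.  The 95% interval is the normal approximation
$E \pm 1.96\sqrt{\mathrm{Var}}$ computed on the coefficient scale and then
exponentiated to the RR scale (the alternative, intervals built directly
on the RR scale, differs only in third-decimal ways at these effect
sizes; the coefficient scale is where the normal approximation is
stated).  $P(\text{RR} > 1)$ mixes per-model draw-based tail
probabilities $\sum_k w_k\,\hat P(\beta_2 > 0 \mid M_k, Y)$; the tail
probability implied by the combined normal is also computable from the
returned moments.

All weight arithmetic happens on the log scale after subtracting the
maximum; a hopeless model may underflow to exactly zero weight, which is
permitted and reported.

# Diagnostics

* **Overdispersion**: Pearson $X^2/(n-p)$ from the deterministic
  maximum-likelihood Poisson fit.  (A deviance-based version of this
  statistic exists; the Pearson form is the common default and is what
  the package uses.)
* **Moran's I permutation test** on the GLM Pearson residuals.  The test
  is one-sided ("greater") by default since CAR random effects are
  introduced to absorb *positive* autocorrelation, with a `two.sided`
  switch; the p-value uses the add-one estimator
  $(1 + \#\{I_\pi \ge I_{obs}\})/(1 + n_{perm})$ so it is never zero.
* **DIC / $p_D$**: $p_D = \overline{D} - D(\bar\eta)$ and
  $\mathrm{DIC} = \overline{D} + p_D$, where the plug-in deviance is
  evaluated at the posterior mean of the **linear predictor**.  This is
  well defined for all three structures, and because $\eta$ is linear in
  the parameters it coincides with plugging in the posterior mean of each
  parameter block.  Deviances keep their normalising constants,
  consistently, so differences between models are meaningful.
* **RMSE**: $\sqrt{n^{-1}\sum_i (Y_i - \hat\mu_i)^2}$ with
  $\hat\mu_i$ the posterior mean of $E_i R_i$ (averaged over draws, in
  chunks, so memory stays bounded).
* **Convergence**: the pipeline gates each model on the potential scale
  reduction factor of $\beta_2$ (default threshold 1.05; configurable,
  with a fail-loud default when a model misses it).

# The synthetic-data generator

No individual-level or zone-level data ship with the package; the
generator produces complete studies with known truth so that every stage
runs end-to-end and recovery can be tested.  What it emulates, and the
reasoning behind the defaults:

* **Geography**: a rook-adjacency lattice, by default $46 \times 46$
  truncated row-major to $n = 2089$ zones -- the size of a West-of-Scotland
  style data-zone system -- with 1 km spacing and centroids jittered off
  cell centres (population-weighted centroids do not sit at geometric
  centres).
* **Population and expected counts**: zone populations uniform on
  500--1000 residents across six age--sex strata.  The stratum rate ladder
  is steep (factor $\approx 3.2$ per stratum, $\approx 300$-fold overall,
  anchored so a regional-profile zone expects $\approx 27$ deaths over a
  seven-year window) because cardio-respiratory mortality is
  overwhelmingly a disease of older strata.  Zone age profiles are
  Dirichlet-distributed around the regional profile, and a small fraction
  (3%) of zones are "city-centre" style with very young profiles.  These
  zones have expected counts of only a few deaths and can realise zero --
  reproducing the zero-SMR zones that real small-area mortality data
  contain -- while the realised SMR distribution keeps mean $\approx 1.07$
  and standard deviation $\approx 0.4$.
* **Deprivation**: six Gaussian domains with a fixed target correlation
  matrix reproducing the strong income--employment--education block,
  moderate crime/housing correlations and a negatively-correlated access
  domain, plus a composite index formed as the equal-weight mean of the
  standardised domains.  The real composite index uses a published
  re-weighting; the models only need *a* composite correlated with its
  domains, so equal weights are used and documented.
* **Exposure**: a "modelled" gridded surface (smooth GP with exponential
  correlation, range 3 km, sill 16, plus a cell-scale component of
  variance 18 representing kilometre-scale source structure -- roads and
  urban fabric -- that a 1 km dispersion map resolves but a smooth trend
  does not), and a "fusion" version formed as an affine recalibration
  plus a GP discrepancy with nugget.  Defaults give NO$_2$-like surfaces
  (mean $\approx 18\,\mu$g m$^{-3}$, zone-level sd $\approx 5$--6,
  modelled--fusion correlation $\approx 0.9$).  Both surfaces aggregate to
  zones by the exponential-distance weighting
  $x_i = \sum_j e^{-d_{ij}}\tilde v_j / \sum_j e^{-d_{ij}}$ over the
  cells in zone $i$, with distances in km (`distance_unit_km: true`; the
  weight $e^{-d}$ is unit-dependent and km matches the 1 km grid), and a
  zone containing no cell centroid takes the value of the nearest cell,
  ties broken by lowest cell index.
* **Counts**: $\phi$ is drawn from the proper Leroux Gaussian
  ($\rho \in [0,1)$ only -- the intrinsic limit is improper and excluded
  from the generator), centred to sum to zero so the intercept is
  identified in recovery tests, and $Y_i \sim
  \text{Poisson}(E_i e^{z_i^\top\beta + \phi_i})$ with an overflow guard
  at $|\eta| > 30$.  Scenario defaults: $\rho = 0.9$, $\tau^2 = 0.15$
  (between the variance scales a Leroux fit typically reports for such
  data, and enough to make the counts strongly overdispersed), true RR
  1.011 per 5 $\mu$g m$^{-3}$ on the modelled surface with income as the
  true confounder, and the intercept calibrated against a target mean
  SMR of 1.066.

What the generator does **not** emulate: real polygon geography (queen
adjacency, unequal zone areas), the dispersion physics behind the
modelled surface, the published re-weighting of the composite index,
measurement-site networks and the fitting of a real calibration model,
and socio-demographic gradients linking deprivation to exposure.
Passing tests therefore demonstrate that the samplers, diagnostics and
averaging machinery are correct and well calibrated under a faithful
statistical caricature of such a study -- not that any particular
epidemiological estimate is reproduced.

# Numerical and design choices

* Distances in km throughout; exposure aggregation weights are convex, so
  zone values always lie within the range of their cells' values.
* The Leroux determinant is evaluated through the spectrum of
  $\mathrm{diag}(W\mathbf 1) - W$, computed once per graph.
* `build_orthogonal_basis` rejects $q$ larger than the count of strictly
  positive eigenvalues (threshold $10^{-10}$) and reports the available
  count; eigenvalues are returned in non-increasing order and
  $\max|M^\top Z| < 10^{-8}$ is an invariant.
* Per-model seeds are a deterministic hash of (master seed, model index),
  so grid results are identical regardless of execution order.
* The recovery tests simulate from the spatial model with i.i.d.
  covariates ($x \sim N(18, 6^2)$, $u \sim N(0,1)$): recovery of a known
  coefficient is a property of the sampler, and an
  identification-friendly design is the standard way to test it.  With
  the study emulator's spatially smooth exposure the same truth is
  recovered but with wider posteriors, as spatial confounding theory
  predicts.
* Problem sizes used by the test-suite and the acceptance script are
  deliberate package choices balancing Monte-Carlo error against runtime:
  recovery at $n = 400$ (20 replicates, 3 chains $\times$ 10{,}000),
  Moran calibration at 500 null replicates $\times$ 499 permutations,
  the conjugate marginal-likelihood check at $J = 50{,}000$, and the
  demonstration grid at $n = 400$ with 3 chains $\times$ 10{,}000 per
  model.

# Known limitations

* The marginal-likelihood estimator is the as-written Monte-Carlo
  average discussed above; its weights should be read as sharp
  goodness-of-fit weights, not calibrated prior-predictive
  probabilities.
* Single-site Metropolis updates mix slowly for very smooth fields;
  the reference protocol's long chains (and the pipeline's PSRF gate)
  are the mitigation.
* The generator draws from the proper Leroux prior only ($\rho < 1$).
* Queen adjacency, non-Poisson likelihoods, BYM-type convolution priors,
  WAIC and cross-validatory checks are out of scope.
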