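---
title: "Spatially-varying coefficient models for lake chlorophyll: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially-varying coefficient models for lake chlorophyll: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(svclake)
```

## The model

Lake chlorophyll *a* (CHL, a proxy for phytoplankton biomass) is classically
predicted from total phosphorus (TP, the limiting nutrient in north-temperate
lakes) and water color (colored dissolved organic matter, a light attenuator
and nutrient carrier). These relationships vary among lakes, and lakes near
one another tend to have more similar relationships than distant lakes.
`svclake` models this with a spatially-varying coefficient (SVC) regression:
for observation $t$ at lake location $s$,

$$
y_t(s) = \tilde{x}_t(s)^\top \tilde{\beta}(s) + x_t(s)^\top \beta + e_t(s),
\qquad e_t(s) \sim N(0, \tau^2),
$$

where $y$ is log10 CHL, $\tilde{x} = (1, \log_{10}\mathrm{TP},
\log_{10}\mathrm{color})^\top$ carries the spatially-varying terms, and $x$
holds space-invariant lake and catchment covariates (log10 maximum depth,
log10 catchment:lake area ratio, catchment agriculture and wetland
proportions, a drainage-connectivity dummy). The residual variance $\tau^2$
absorbs measurement error and within-lake temporal variability; repeated
observations of one lake share a single coefficient vector
$\tilde{\beta}(s)$, and time enters only through replicate rows.

The three coefficient surfaces follow a multivariate Gaussian process with
mean $\tilde{\beta}_\mu$ and a linear-model-of-coregionalization (LMC)
covariance: $\tilde{\beta}(s) = \tilde{\beta}_\mu + A\, v(s)$, where the
$v_j(s)$ are independent unit-variance Gaussian processes with exponential
correlation $\exp(-\phi_j d)$ and $A$ is lower triangular with positive
diagonal. $K = AA^\top$ is the between-coefficient covariance at distance
zero; each coefficient inherits its own decay rate, so the TP and color
surfaces can vary at different spatial scales. The *effective spatial range*
is the distance at which correlation drops to 0.05, $-\log(0.05)/\phi
\approx 3/\phi$; `effective_range()` and `decay_for_range()` convert both
ways. The exponential family is the package's choice — only a "decay
parameter" is assumed by the model class, and the exponential makes the
range closed-form; a Matérn family is a natural extension point.

## Sampler design

`fit_svc()` runs a Metropolis-within-Gibbs sampler on the latent-process
parameterization $(\gamma, v, \tau^2, \phi, A)$ with
$\gamma = (\tilde{\beta}_\mu, \beta)$:

1. $\gamma$ — conjugate Gaussian given the field contribution and $\tau^2$.
2. $v$ — one joint conditional Gaussian draw of the stacked $mq$ latent
   field (prior precision block-diagonal in the per-process correlation
   inverses, data precision site-diagonal through the mixed design
   $\tilde{X}A$).
3. $\tau^2$ — inverse gamma with shape $+\,n/2$ and scale $+\,\mathrm{SSR}/2$.
4. each $\phi_j$ — random-walk Metropolis on $\log\phi_j$, accepted by the
   likelihood with process $j$ *integrated out* (a site-level Woodbury
   identity reduces this to two $m \times m$ factorizations); on acceptance
   $v_j$ is redrawn from its conditional under the new decay. We first
   implemented the cheaper update that conditions on the sampled field; it
   mixes so poorly between short- and long-range explanations of the data
   that chains initialized neutrally collapse into a white-field mode with
   inflated $A$ and vanishing $\tau^2$. The collapsed move removes that
   coupling and is the package default.
5. each element of $A$ — random-walk Metropolis (log scale on the diagonal)
   whose data contribution is a pure likelihood ratio, $O(n)$ per element.

Proposal scales adapt toward a 0.35 acceptance rate during burn-in only
(Robbins–Monro, frozen afterward so the retained chain is ergodic).
Convergence is summarized by split-chain potential-scale-reduction factors
on all scalar parameters (`tidy(fit)$rhat`, `glance(fit)$max_rhat`).
Defaults are 25,000 iterations, 15,000 burn-in, thinning 10; examples in
this vignette and the package tests use much shorter, problem-scaled runs.

### Priors

The source analysis this package operationalizes does not state priors, so
the defaults in `svc_priors()` are weakly informative and scale-aware:
$N(0, 10^4)$ on every mean coefficient, inverse-gamma(2, 0.1) on $\tau^2$,
half-normal(1) diagonals and normal(0, 1) off-diagonals for $A$, and for
each $\phi_j$ a uniform prior whose support is derived from the observed
geometry: decay rates between $-\log(0.05)/d_{95}$ and $-\log(0.05)/d_{5}$,
with $d_5, d_{95}$ the 5th and 95th percentiles of inter-site distances.
Range parameters of Gaussian processes are notoriously weakly identified —
on 100–150-site problems we measured the collapsed likelihood to vary by
only 1–2 nats across the whole plausible decay interval for the short-range
processes — so posterior effective ranges are substantially shaped by this
support; it restricts them to the bulk of the observed spatial lags, which
is the standard field heuristic. Reported ranges should be read with that
in mind, and users with genuine prior knowledge should set `phi_lower` /
`phi_upper` explicitly.

### Numerical choices

Correlation matrices receive a relative diagonal jitter of `1e-8` before
factorization; exactly coincident distinct lakes are deterministically
jittered 0.001 km apart by `build_model_frame()` with a loud warning.
Stacked fields are coefficient-major (all sites for coefficient 1, then 2,
…). Chains are bit-reproducible given `mcmc_control(seed = )`.

## Model comparison and predictive scoring

`compute_dic()` reports the posterior mean deviance $\bar{D}$, the plug-in
deviance $\hat{D}$ at the posterior means of the *full* parameter set —
including the site-level coefficients, which is why SVC models carry
effective parameter counts in the hundreds while a vague-prior linear
regression shows $p_D \approx 4$ — and $\mathrm{DIC} = \bar{D} + p_D$.
The plug-in convention (conditional focus) is a documented choice; $p_D$
magnitudes should be compared only qualitatively across conventions.

`posterior_predict()` does composition sampling for holdout rows: training
lakes use their sampled coefficients; unseen lakes get coefficients kriged
per posterior draw from each latent process's conditional, so a far-away
lake reverts to $\tilde{\beta}_\mu$ with full marginal variance.
`score_holdout()` evaluates, on the log10 modeling scale, RMSPE of the
predictive means, the mean continuous ranked probability score (closed-form
Gaussian `crps_gaussian()` and a sample-based estimator `crps_sample()` for
the draws themselves), and the central 95% interval coverage (PCI, %) and
width (PIW).

## The synthetic-data generator

`simulate_lakes()` emulates the statistical structure the analysis assumes,
so every stage is testable without the original data: ~840 lakes over a
340 × 340 km extent (median nearest-neighbour spacing ≈ 6 km at that
density); right-skewed log-normal covariates matched by median and spread
to the study population (TP and color medians 14, depth 9.2 m, lake area
55 ha, CA:LK 10); a 72:28 drainage:isolated mix; ~27% of lakes revisited
with Poisson-many extra samples (≈30 on average), TP and color redrawn per
visit around the lake-level value (sd 0.15 log10 units) while coefficients
stay fixed; and coefficient fields drawn from the LMC prior with generating
values equal to the fitted model's headline estimates — domain means
$(-0.36, 0.698, -0.02)$, $\tau^2 = 0.63$, effective ranges ≈ 33, 26 and
216 km. The default $A$ gives coefficient-field standard deviations of
0.30, 0.20 and 0.15 with mild cross-correlation, consistent with the
spread of lake-specific slopes the fitted model reports. Lake areas are
clamped to (4.3, 9000) ha so a default simulation passes the area filter
by construction.

What the generator deliberately does *not* emulate: the geographic
footprint of real state boundaries, spatially structured land cover,
covariate confounding (covariates are independent by default), and stream
topology. Passing tests therefore demonstrate correctness of the machinery
under the model's own assumptions, not robustness to real-data violations
of them.

`simulate_filter_fixture()` produces a small table with known violations of
each inclusion rule and an answer key, used to test the filter attribution
logic.

## Data pipeline conventions

Inclusion rules follow the study population definition: lake area strictly
between 4 and 10,000 ha (boundary values excluded), sampling date inside
June 15 – September 15 inclusive, CHL/TP/color measured in the same
sampling event (all present on one row; no cross-date matching is
attempted, and multiple same-day rows are all kept), and maximum depth
known. Dropped rows are attributed to the first failing rule in the order
area, season, triplet, depth; the kept set is order-invariant.
`split_holdout()` assigns observations (not lakes) at random with
`floor(fraction × n)` holdout rows, so a revisited lake may appear in both
partitions. `project_coordinates()` provides an equidistant conic
projection (spherical earth) centred on the data's bounding box; within a
few hundred km it preserves pairwise distances to well under 1%, and
synthetic data bypass projection with native km coordinates. Because the
original analysis's projection is unstated, effective-range comparisons to
published values are approximate at the few-percent level.

## Post-hoc summaries

`coefficient_field()` tabulates per-lake posterior means, sds and central
95% intervals; a lake's relationship is *positive* when the interval lies
above zero, *negative* below, *null* otherwise (intervals touching zero are
null). `translate_effect()` converts a log10–log10 slope $b$ to a
natural-scale effect via the power-law derivative $b \cdot
\mathrm{CHL}/\mathrm{TP}$ evaluated at a reference point; per-lake
translations use the lake's median observed CHL and predictor, which
reproduces lake-specific effect ranges without extra modeling. Surfaces
are interpolated by inverse-distance weighting (power 2) — deterministic
and parameter-light, appropriate for presentation surfaces rather than
inference; kriging would add assumptions the display does not need.
Correlations with lake covariates use Pearson tests with unadjusted
two-sided p-values (a multiplicity note is emitted), and drainage-versus-
isolated contrasts use Welch two-sample t-tests, both via base R.

## Problem sizes used in tests and the acceptance script

The package's checks run at deliberately reduced sizes chosen to keep the
full suite desk-sized while preserving the structure being verified:
parameter-recovery replicates use 150 lakes (~1,300 observations) with
2,200-iteration chains across 10 seeds; model-comparison and coverage
checks use 100–150 lakes; the acceptance script fits one SVC and one
non-spatial model to a 120-lake dataset (~1,000 observations) with
2,600-iteration chains, and exhibits the pipeline arithmetic on a
full-size 7,395-row simulation. With these sizes, 95% credible intervals
cover generating mean coefficients and $\tau^2$ in at least 8 of 10
replicates, and across-replicate median effective ranges recover the
generating short-range values within a factor of 2.5 — a deliberately wide
band, reflecting how weakly spatial ranges are identified at these sizes.

## Known limitations

- Dense $mq \times mq$ factorizations limit practical problems to roughly
  a thousand lakes; predictive-process or other low-rank approximations are
  out of scope.
- The correlation family is exponential and isotropic; no anisotropy or
  nonstationarity.
- The ambiguity in reporting the spread of lake-specific TP slopes (posterior
  sd across lakes versus mean posterior sd) is resolved by reporting both:
  `coefficient_field()` returns per-lake posterior sds, and the sd of the
  per-lake posterior means across lakes is one `dplyr::summarise()` away.
- Temporal structure is not modeled (replicate rows are exchangeable given
  the lake); residual time trends should be checked externally.
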