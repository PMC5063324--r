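# svclake

Bayesian **spatially-varying coefficient (SVC) regression** for macroscale
lake water quality, with the supporting pipeline to make such an analysis
reproducible end to end: filtering and transforming lake observation tables,
train/holdout partitioning, a Metropolis-within-Gibbs sampler for the SVC
model, DIC model comparison, posterior predictive scoring, coefficient-surface
summaries, and a synthetic lake-data generator so every stage is verifiable
without access to any particular monitoring database.

## Who this is for

Limnologists and spatial statisticians asking whether the effects of
total phosphorus (TP) and water color on lake chlorophyll *a* (CHL) — the
nutrient–water color paradigm — differ from lake to lake, at what spatial
scale those differences are organized, and whether letting the coefficients
vary over space improves prediction.

## The model

For observation *t* at lake location *s* (log10 scale throughout):

```
y_t(s) = x̃_t(s)ᵀ β̃(s) + x_t(s)ᵀ β + e_t(s),      e_t(s) ~ N(0, τ²)
```

with `x̃ = (1, log10 TP, log10 color)ᵀ`. The three coefficient surfaces
`β̃(s)` follow a multivariate Gaussian process with mean `β̃_μ` and a
linear-model-of-coregionalization covariance: `β̃(s) = β̃_μ + A v(s)`,
where the `v_j` are independent unit GPs with exponential correlation
`exp(−φ_j d)` and `A` is lower triangular. Each coefficient gets its own
**effective spatial range** `−log(0.05)/φ_j ≈ 3/φ_j`, the distance at which
spatial correlation in that coefficient becomes negligible. Fixed covariates
(depth, catchment:lake ratio, land cover, connectivity) enter through `β`.

Candidate models compare a non-spatial regression against SVC variants with
and without the fixed covariates, ranked by DIC and by holdout RMSPE, CRPS,
95% predictive interval coverage (PCI) and width (PIW).

## Worked example

```r
library(svclake)

# 1. simulate a study-structured dataset (or read your own CSV with the
#    same columns and project lon/lat with project_coordinates())
obs <- simulate_lakes(sim_config(n_sites = 120, extent = c(300, 300)),
                      seed = 21)

# 2. inclusion rules, model frame, 90/10 split
kept  <- apply_filters(obs$data, filter_config())
frame <- build_model_frame(kept)
sp    <- split_holdout(frame, fraction = 0.10, seed = 22)

# 3. fit the SVC model and the non-spatial benchmark
fit <- fit_svc(sp$train, control = mcmc_control(n_iter = 2600, n_burn = 1300,
                                                n_thin = 2, seed = 23))
ns  <- fit_nonspatial(sp$train, control = mcmc_control(n_iter = 4000,
                                                       n_burn = 1000,
                                                       n_thin = 3, seed = 24))
tidy(fit)
#> # A tibble: 10 × 7
#>    term                type     estimate std.error conf.low conf.high   rhat
#>  1 intercept           svc_mean  -0.443     0.235   -0.890     0.0210  1.02
#>  2 log_tp              svc_mean   0.623     0.165    0.306     0.945   1.04
#>  3 log_color           svc_mean   0.213     0.177   -0.132     0.564   1.01
#>  4 tau2                variance   0.650     0.0345   0.589     0.723   0.999
#>  5 phi_intercept       decay      0.0485    0.0161   0.0138    0.0715  1.00
#>  ...
#>  9 eff_range_log_tp    range     60.8      47.8     42.1     248.     NA
```

Here the TP slope's domain mean (0.62, interval covering the generating
0.698), the residual variance (0.65 vs generating 0.63) and the effective
ranges (tens to hundreds of km) are posterior summaries; `rhat` is the
split-chain convergence factor (≈1 is good).

```r
# 4. model comparison and holdout scoring
compute_dic(fit, sp$train)$DIC   # 1892 — lower DIC is better
compute_dic(ns,  sp$train)$DIC   # 2103: the SVC model wins by ~211
pred <- posterior_predict(fit, sp$holdout, n_draws = 300, seed = 25)
score_holdout(pred, sp$holdout)
#> # A tibble: 1 × 4
#>   rmspe  crps   pci   piw
#>   0.829 0.470  92.9  3.24

# 5. lake-level science: who has positive/negative/null color effects,
#    what does a 1 ug/L TP increase do in natural units, and how do the
#    surfaces look?
field <- coefficient_field(fit)
classify_significance(field)
translate_effects(field, sp$train$data, term = "log_tp", predictor = "tp")
autoplot(interpolate_surface(field, "log_tp", cell_km = 5))
autoplot(field, what = "significance")
correlate_with_covariates(field, kept,
                          c("max_depth", "prop_agriculture", "prop_wetland"))
contrast_by_connectivity(field, kept)
```

A PCI of 92.9 means 92.9% of held-out observations fell inside their 95%
predictive intervals; RMSPE 0.83 is on the log10 CHL scale and beats the
non-spatial benchmark (0.91) on the same split.

## Package tour

| area | functions |
|---|---|
| data pipeline | `project_coordinates`, `filter_config`, `apply_filters`, `filter_log`, `build_model_frame`, `split_holdout`, `nearest_neighbor_summary` |
| GP / LMC core | `distance_matrix`, `spatial_correlation`, `effective_range`, `decay_for_range`, `lmc_params`, `lmc_covariance`, `sample_mvgp` |
| inference | `svc_priors`, `mcmc_control`, `fit_svc`, `fit_nonspatial`, `svc_log_likelihood`, `tidy`, `glance`, `plot_traces` |
| evaluation | `compute_dic`, `posterior_predict`, `crps_gaussian`, `crps_sample`, `score_holdout` |
| post-analysis | `coefficient_field`, `classify_significance`, `translate_effect(s)`, `interpolate_surface`, `correlate_with_covariates`, `contrast_by_connectivity`, `autoplot` |
| synthetic data | `sim_config`, `simulate_sites`, `simulate_lakes`, `simulate_filter_fixture` |

The methods vignette (`vignettes/svc-lake-chlorophyll.Rmd`) documents the
model, the sampler design (including why the decay-rate updates are
collapsed), prior choices and their consequences for range estimates, the
generator's realism and limits, and the problem sizes the checks run at.
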