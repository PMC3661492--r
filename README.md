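# hurdlecatch

Bayesian estimation of protected-species bycatch in a partially observed
trawl fishery.

Government observers ride along on only a fraction of commercial trawl
tows, so the captures they record are a sample, not a census. This package
estimates **total** captures — here motivated by common dolphin
(*Delphinus delphis*) bycatch in the large-vessel mackerel fishery off the
west coast of New Zealand's North Island — by fitting a capture model to
observed tows and extrapolating over the unobserved effort, using only
covariates that fishers report on every tow.

## The model

A two-stage Bayesian **hurdle model**:

1. **Capture-event stage.** A hierarchical logistic regression for whether
   any capture occurs on tow *i*:

   logit(p_i) = α_t(i) + Σ_k β_k x_ik

   with random fishing-year effects α_t ~ N(μ_α, σ_α) and per-tow
   covariates x (headline depth, log tow duration, light condition,
   sub-area in the final model). Priors: diffuse normals (SD 100) on β and
   μ_α, half-Cauchy(25) on σ_α.

2. **Event-size stage.** Counts on capture events follow a zero-truncated
   Poisson with size λ (uniform prior on [0.5, 30]):

   P(n | event) = λⁿ e^{−λ} / ( n! (1 − e^{−λ}) ),  n ≥ 1.

Totals per fishing-year × vessel group are the observed captures plus
event/count simulations on every unobserved tow, drawn per posterior
sample (Bernoulli(p_i), then ZTP(λ)), summarised as means with equal-tailed
95% credible intervals.

Around the model sit the working parts of the analysis: covariate
engineering (civil-twilight and lunar-illumination light classification,
headline depth from gear geometry, night hours, bathymetry lookup),
stepwise AIC covariate selection with a 1% deviance-reduction stopping
rule, an adaptive Metropolis-within-Gibbs sampler with split-R̂/ESS
diagnostics, posterior predictive checks of captures per event, and a
synthetic fleet generator that reproduces the study conditions so the
entire pipeline is testable without the confidential fishery data.

## Worked example

Simulate a 3-year fleet, fit the hurdle model, and estimate total captures:

```r
library(hurdlecatch)

cfg <- scenario_config(n_years = 3, first_year = 2004,
                       effort_per_year = c(1200, 1500, 1400),
                       coverage = c(0.35, 0.25, 0.40))
tows  <- simulate_captures(generate_effort(cfg, seed = 1), cfg, seed = 2)
parts <- apply_observer_coverage(tows, cfg$coverage, seed = 3)

cov  <- derive_covariates(parts$observable)
dm   <- build_design_matrix(cov, final_model_specs())
post <- sample_posterior(dm, prior_spec(),
                         mcmc_config(n_burn = 2000, n_iter = 6000, thin = 6,
                                     n_chains = 2, seed = 4))
coefficient_table(post, exponentiate_factors =
                    c("light_light", "light_black", "subarea_south"))
#>   term              mean    q2.5     q50   q97.5
#> 1 headline_depth -0.0579 -0.0853 -0.0575 -0.0335
#> 2 log_duration    2.01    0.910   2.05    2.95
#> 3 light_light     0.0538  0.0139  0.0483  0.130
#> 4 light_black     0.899   0.301   0.808   2.06
#> 5 subarea_south   0.508   0.208   0.467   1.01
#> 6 lambda          2.06    1.60    2.05    2.59

est <- collapse_to_years(predict_group_totals(post, dm, "year_vessel", seed = 5))
annual_summary_table(cov, est)
#>   fishing_year effort observed_captures observed_rate est_captures est_lwr est_upr
#> 2      2004-05   1199                42         14.00          155      99     221
#> 3      2005-06   1501                19          3.17           51      28      84
#> 4      2006-07   1398                28          5.73           89      56     134
```

Reading the output: the headline-depth coefficient is per metre on the
log-odds scale, so `halving_distance(-0.058)` ≈ 12 m is the extra depth
that halves the event probability in this realisation; factor rows are
exponentiated (tows hauled in the light have ~0.05× the odds of a capture
event relative to dark hauls here); `lambda` ≈ 2.06 is the mean ZTP size —
typical capture events involve about two animals. The simulation's true
total was 365 captures; the fitted model estimated 295 with 95% CI
[221, 383]. (A tiny extra fishing-year row can appear when a tow starts
just before a 1 October boundary.) Split-R̂ for all parameters in this run
was ≤ 1.003.

The same stages are available as a file-based pipeline with manifests and
resumability: `run_simulate()`, `run_prepare()`, `run_select()`,
`run_fit()`, `run_estimate()`, `run_report()`.

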