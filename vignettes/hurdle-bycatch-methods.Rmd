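---
title: "Estimating trawl bycatch from partial observer coverage: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trawl bycatch from partial observer coverage: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protected-species bycatch in commercial trawl fisheries is observed only on
the fraction of tows that carry a government observer. In the fishery this
package is built around — large (>90 m) vessels targeting jack and blue
mackerel off the west coast of New Zealand's North Island — observer
coverage fluctuated between roughly 7% and 70% of tows per fishing year.
Estimating *total* captures of common dolphin therefore means fitting a
capture model to the observed tows and extrapolating over the unobserved
effort, using only covariates that fishers themselves report (gear
geometry, times, positions, target species, catch), since those are the
only fields available on unobserved tows.

Capture data of this kind are doubly awkward: the vast majority of tows
catch nothing, and when a capture event does occur it frequently involves
several animals at once (schools feed around the net). A single
count-distribution model handles neither feature well.

## The two-stage hurdle model

The package separates the two processes.

**Stage 1 — does a capture event occur?** A hierarchical logistic
regression over tows $i$:

$$\operatorname{logit}(p_i) = \alpha_{t(i)} + \sum_k \beta_k x_{ik},$$

where $\alpha_t$ is a random effect for fishing year $t$ (1 October–30
September), $\alpha_t \sim N(\mu_\alpha, \sigma_\alpha)$, and $x_{ik}$ are
per-tow covariates. Year effects absorb annual variation in dolphin
abundance or vulnerability that the covariates cannot explain.

**Stage 2 — how many animals, given an event?** Counts on event tows
follow a zero-truncated Poisson (ZTP) with size $\lambda$:

$$P(n \mid \text{event}) = \frac{\lambda^n e^{-\lambda}}{n!\,(1 - e^{-\lambda})},
\qquad n \ge 1.$$

Truncation reflects the hurdle structure: an event, by definition, caught
at least one animal. A covariate-dependent $\lambda$ is deliberately not
offered: exploratory fits show no consistent covariate signal in event
sizes, and the extra parameters only widen the totals.

**Priors.** Diffuse normals (SD 100) on each $\beta_k$ and on
$\mu_\alpha$; a half-Cauchy with scale 25 on $\sigma_\alpha$; a uniform on
$\lambda$ over $[0.5, 30]$. The half-Cauchy is placed on the *standard
deviation* of the year effects, following the usual weakly-informative
recommendation for hierarchical scale parameters; the scale of 25 is far
into the flat region for effects that live on the logit scale, so it is
effectively uninformative here. All of these are `prior_spec()` arguments.

**Extrapolation.** For each posterior draw and each unobserved tow, an
event is simulated from $p_i$ and, if it occurs, a count from
$\text{ZTP}(\lambda)$ — the same draw supplies both, so the uncertainty in
$p$ and $\lambda$ propagates jointly. Totals per fishing-year × vessel
group are the observed captures plus the simulated captures; year totals
are vessel sums within each draw, so intervals respect the joint
posterior. Totals can never fall below what observers actually reported.
Intervals are equal-tailed 2.5/97.5% posterior quantiles, rounded only at
render time.

## Covariate engineering

All candidate covariates are derivable from fisher-reported fields:

* **Headline depth** (m): ground-line depth minus headline height — the
  depth of the top of the net opening. Records where the difference is
  non-positive are invalid gear records, excluded and counted.
* **Depth factor**: bottom depth < 210 m is "shallow" (strict), else
  "deep"; bottom depth comes from a per-tow column or a nearest-cell
  lookup in a plain-text raster, taking the minimum of the start and end
  positions.
* **Light condition**: a three-level factor built from civil twilight and
  the lunar phase. *Light* — hauled between civil dawn and dusk, or
  between dusk and local midnight on a moonlit night; *dark* — between
  dusk and midnight on a dark night, or between midnight and dawn on a
  moonlit night; *black* — between midnight and dawn on a dark night. A
  night is moonlit when strictly more than 17% of the lunar disc is
  illuminated, evaluated at the haul time; the dusk→dawn interval
  containing the haul defines "the night". Midnight is 00:00 on the local
  civil clock (default UTC+12), matching how haul times are recorded, not
  solar midnight.
* **Night hours**: the tow's duration falling between civil dusk and the
  following civil dawn, summed over nights spanned. The covariate's
  conventional description ("hours between dawn and dusk") literally reads
  as daylight; it is implemented as night-time hours, which is what the
  name and the model's use of it mean.
* **Transforms**: catch weight, tow duration, night hours, bottom depth
  and fishing depth enter both raw and log-transformed; one tonne is added
  to catch weight and one hour to night hours before the log (so a zero
  maps to zero); tow duration takes a plain log with no offset and must be
  positive. A variable and its log transform are never allowed in the same
  model — they are near-collinear and the step search would otherwise
  thrash between them.
* Factors are treatment-coded: light against *dark*, sub-area against
  *north*.

The ephemeris behind twilight and lunar illumination is implemented from
low-precision closed-form series: geometric solar position good to about
0.01° and a lunar phase angle good to about 0.5°. For a 6° twilight
crossing and a 17% illumination threshold this is orders of magnitude more
precision than needed, and it keeps the package dependency-free.
Refraction and ΔT are ignored. Twilight instants are solved by an
hour-angle fixed-point iteration to below one second, and the tests hold
them within two minutes of an independently implemented reference
algorithm. Latitudes beyond ±66° are refused rather than mishandled: the
classification logic assumes every date has a dawn and a dusk, which is
true throughout the study region.

The sub-area split at 39°18′ S assigns the boundary latitude itself to
*south* — an arbitrary but deterministic convention, immaterial at data
resolution. The study area is a configurable rectangle (171° E to
173°2.8′ E, 41° S to a northern bound standing in for the EEZ): the true
EEZ polygon adds nothing to the model and would drag in GIS machinery.

## Covariate selection

A greedy bidirectional step search over whole candidate terms starts from
the intercept-only binomial GLM (maximum likelihood, IRLS). At each step
every single addition and removal is fitted and the move with the greatest
AIC reduction wins; ties break lexicographically so the search is
invariant to candidate order. An *addition* must also cut the current
model's residual deviance by more than 1% (`stop_frac`) to be applied —
an addition failing that rule ends the search. This keeps statistically
"significant" but explanatorily trivial covariates out of the final model.
The 1% is interpreted relative to the current model's residual deviance,
and the search runs without year terms: selection asks which covariates
carry signal, the hierarchy then absorbs annual variation at fitting time.
Removals are accepted on AIC improvement alone — a removal increases
deviance by construction, so a deviance-reduction test cannot apply to it.

## MCMC

The posterior is sampled by componentwise adaptive random-walk Metropolis
("Metropolis within Gibbs"): Gaussian proposals for each $\beta_k$,
$\alpha_t$, $\mu_\alpha$ and $\log \sigma_\alpha$ (with the Jacobian
accounted for), and for $\lambda$ on its natural scale with reflection at
the uniform bounds. During burn-in each coordinate's proposal scale is
reviewed every 50 sweeps and nudged by a factor of 1.5 until its
acceptance rate sits in [0.2, 0.5]; scales are then frozen so the kept
draws target the exact posterior. Initial values: $\beta = 0$, year
effects and $\mu_\alpha$ at the logit of the overall event rate,
$\sigma_\alpha = 1$, $\lambda$ at the mean count among events. Chain $c$
is seeded `seed + c`, so runs are reproducible and chains independent.

The default protocol (`mcmc_config()`) is 10 000 burn-in sweeps, 100 000
further sweeps thinned to every 20th, two chains — 5000 kept draws per
chain. Convergence is checked with split-$\widehat{R}$ (each chain halved,
so within-chain drift registers) and an autocorrelation ESS truncated at
the first negative adjacent-lag pair sum; both are cross-checked against
the CODA implementations in the test suite. A posterior predictive check
compares the observed distribution of captures per event against
event-size tables simulated from the $\lambda$ draws
(`ppc_event_size()`).

Year effects for years with observed effort but no observed tows are drawn
from the hierarchy — predictions for such years are honest extrapolation
through $(\mu_\alpha, \sigma_\alpha)$ and are correspondingly wide.

## The synthetic fleet

The real effort and observer records are confidential, so the package
ships a generator (`scenario_config()`, `generate_effort()`,
`simulate_captures()`, `apply_observer_coverage()`) whose defaults *are*
the study conditions: 16 fishing years with the published annual effort
(23 499 tows in total) and observer-coverage fractions; seven main vessels
splitting effort evenly (the published record shows seven vessels carrying
over 95% of effort, but per-vessel shares are only available graphically);
effort concentrated in October–December; headline depth a two-component
mixture (60% shallow: mean 30 m SD 15; 40% deep: mean 90 m SD 40;
truncated above 5 m) *coupled to the diel cycle* so that night tows are
shallower — reproducing the confounding between headline depth and light
condition that makes covariate attribution genuinely hard; tow duration
log-normal with median 4 h; true coefficients at the published posterior
means (headline depth −0.033 m⁻¹, log duration 1.470, light ln 0.177,
black ln 1.078, south ln 0.539), $\lambda = 2.1$, and year-effect
hyperparameters $\mu_\alpha = -3.4$, $\sigma_\alpha = 0.6$, chosen so the
realised study-wide event rate sits near the observed 0.88 events per 100
tows with year-to-year variation of the magnitude the annual summary
shows. Observer coverage is simple random sampling of tows within each
year; trip-clustered coverage is deliberately not the default — it would
change variance, not bias, and the simple design keeps the design-based
properties exact.

What the generator does *not* emulate: spatial school structure, dolphin
population dynamics, vessel-specific behaviour (the fleet is modelled as
coherent, mirroring the finding that a vessel effect was not supported),
observer mis-detection, and reporting errors in fisher records. Tests
passing on this fleet therefore demonstrate that the pipeline recovers
what it assumes — correct inference under the stated model — not that the
model is true of any real fishery.

## Verification strategy and problem sizes

The test suite works at deliberately scaled-down sizes so the whole suite
runs in minutes:

* **Exact arithmetic**: published annual effort × coverage reproduces the
  printed observed capture rates (e.g. 10.37 per 100 tows in 2003–04);
  $\ln 2 / 0.033 \approx 21$ m is the headline-depth halving distance;
  inverting the ZTP mean identity at 119 dolphins over 50 events gives
  $\lambda = 2.1$ to one decimal.
* **Quadrature oracle**: on a two-parameter logistic toy the sampler's
  posterior mean and SD match dense-grid numerical integration within 3%.
* **Parameter recovery**: 20 replicates of a 4-year × 1000-tow fleet at
  30% coverage, short chains (1000 burn-in, 500 kept × 2 chains); the true
  headline coefficient, $\lambda$, and the true total captures each fall
  inside their 95% intervals in at least 18 of 20.
* **Selection power**: 50 replicates of 5000 fully observed tows. The
  baseline event rate for this experiment is raised (to roughly 20%)
  rather than left at the fishery's sub-1% rate: selection power is a
  function of the number of events, and at 5000 tows the fishery rate
  would yield ~40 events — far fewer than the ~5650 observed tows' worth
  of information the original selection had. At the raised rate the
  weakest true effect (sub-area, odds ratio 0.54) carries a deviance
  reduction measurably above the 1% stopping rule, and each of the four
  true covariates is recovered in ≥80% of replicates.
* **Distribution-level checks**: the ZTP inverse-CDF sampler matches the
  pmf within 3 SE per bin; the ephemeris matches an independent reference
  implementation within 2 minutes (twilight) and catalogued syzygies
  within 0.02 (lunar fraction).

## Numerical choices and degenerate inputs

* Bernoulli log-likelihoods use `log1p(exp(η))` with a linear branch for
  η > 30; the ZTP normaliser uses `expm1`, so small $\lambda$ is stable,
  and the ZTP stage collapses to sufficient statistics
  ($\sum n_i$, number of events, $\sum \log n_i!$) inside the sampler.
* ZTP sampling is exact inverse-CDF over the pmf — no rejection, no
  approximation.
* Perfect separation in a GLM is detected as runaway coefficients
  (|β| > 30) and flagged; singular designs error naming the collinear
  columns; an all-missing design errors rather than silently shrinking.
* Zero-capture years render blank observed rates but still receive
  estimates; 100% coverage collapses intervals to the observed count.
* The one ambiguity the linker refuses to resolve silently: two observer
  records matching the same tow is an error listing the records, because
  silently dropping one would bias observed captures downward.

## Known limitations

* The rectangle study area and even per-vessel effort shares are
  simplifications; both are configurable.
* Observed-tow counts reconstructed from printed coverage percentages can
  be off by one tow per year, which shifts a printed rate by ±0.01 — the
  package always prefers data-derived counts when records are available.
* The sampler is plain Metropolis-within-Gibbs: adequate for this
  posterior (a few dozen dimensions, well-conditioned), but chain lengths
  in the default protocol are sized for it; gradient-based samplers would
  thin better per CPU-second on larger covariate sets.
* Totals assume observers record captures without error on observed tows;
  there is no detection-failure stage, by design.
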