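---
title: "Methods: footprint-mediated resource selection across a park closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint-mediated resource selection across a park closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

Protected-area mammals experience two distinct kinds of human disturbance:
permanent infrastructure (the "human footprint": roads, trails, car parks,
buildings, campgrounds) and the transient presence of people. A park
closure separates the two — the infrastructure stays, the people vanish.
The package quantifies third-order habitat selection (selection of
locations within an established home range) relative to a footprint index,
in an open year (2019) and a closure year (2020), and then asks whether an
individual's *exposure* to the footprint predicts its selection for it — a
functional response — and whether that relationship changed with the
closure.

## The footprint index

Each infrastructure class $c$ contributes an influence
$w_c e^{-d_c/s_c}$ at a cell whose centre lies at distance $d_c$ (m) from
the nearest feature of that class. Influences combine by the saturating
union

$$F = 1 - \prod_c \left(1 - w_c e^{-d_c/s_c}\right),$$

which is symmetric in class order, monotone in every influence, bounded in
$[0,1]$ without rescaling, and equal to a lone class's influence exactly. A
weight-normalised sum is available (`aggregation = "weighted_sum"`) for
sensitivity analyses. Defaults (weight, decay scale in m): building (1.0,
500), campground (0.9, 500), parking (0.8, 500), road (0.8, 750), trail
(0.4, 250). These rank permanent, high-occupancy structures above trails
and give roads the longest reach; all are configurable through
`feature_class_params()`, since any particular weighting is a modelling
choice, not a measurement. Distances are Euclidean from cell centres, so a
cell reads 0 exactly when a feature passes through its centre; this keeps
the raster consistent with its brute-force oracle at 30 m discretisation.

The land-cover distance covariates use the same decay form with a fixed 750
m scale, $y = e^{-x/750}$: the influence drops steeply over the first 500 m
and reaches 5% of its initial value at 2.25 km, after which cover-type
distance differences are ecologically negligible at home-range scale.

## Track preparation

* **Error screen.** Per individual, a fix is removed if it duplicates the
  previous retained timestamp (tolerance 0 s by default) or implies a
  straight-line speed above 10 m/s from the previous retained fix — a
  standard telemetry screen; the threshold is per-species configurable.
  Every removal is logged with a machine-readable reason, and kept plus
  dropped equals the input.
* **Resampling.** Tracks faster than the 4 h target are thinned by keeping,
  for each successive target time, the nearest fix within ±30 min (ties to
  the earlier fix), re-anchoring at the kept fix. Tracks whose median
  interval already meets the target are returned unchanged, preserving the
  native schedule of low-rate collars. The operation is idempotent. A 24 h
  target reproduces the coarse-resolution sensitivity configuration.
* **Windows.** The closure window is specified for 2020 and mirrored onto
  the identical month-days of 2019 (default 1 April–28 May, a 58-day
  closure). Clipping uses closed intervals; the boundary instant belongs to
  the window.
* **Inclusion.** An individual-year enters the analysis with at least 30
  retained fixes (configurable; 2 is the hard floor), at most half its
  fixes outside the park, and a home-range mean footprint of at least
  0.001 — animals with essentially no footprint in their range carry no
  information about footprint selection. The numeric cutoffs are exposed in
  `inclusion_thresholds()` because any specific value is a judgement call.

## Home ranges and the used/available design

The 95% KUD uses a bivariate normal kernel (`MASS::kde2d`) with the
normal-scale reference bandwidth per axis, evaluated on a grid four times
finer than the 30 m rasters, padded by one bandwidth so the isopleth cannot
be clipped. The home range is the smallest-density contour containing 95%
of the discretised probability mass, possibly several disjoint rings;
degenerate inputs (fewer than 5 fixes, coincident or colinear fixes) are
errors. Available points are drawn uniformly within the isopleth by
rejection sampling from its bounding box — exactly `ratio` (default 50) per
used point — optionally intersected with the raster extent for edge
animals.

Covariate transforms are applied in a fixed order: land-cover decay first,
then centring/scaling per population (n-divisor standard deviation), pooled
over used and available rows of **both** years, so 2019 and 2020
coefficients sit on a common scale (the cross-year contrasts require
this). The footprint covariate is never scaled: its coefficient stays
interpretable as log-odds per unit of the [0, 1] index. The correlation
screen runs on available rows only (it characterises the habitat domain,
not use) and reports |r| > 0.7 pairs without dropping anything.

## The hierarchical RSF

For one population with individual-years $j$ and points $i$:

$$\mathrm{used}_i \sim \mathrm{Bern}(p_i), \quad
\mathrm{logit}(p_i) = \beta_{\mathrm{int}[j]}
 + \beta_{\mathrm{fp}[j]}\,\mathrm{footprint}_i
 + \beta_{\mathrm{elev}[j]}\,\mathrm{elevation}_i
 + \beta_{\mathrm{slope}[j]}\,\mathrm{slope}_i
 + \sum_c I_{c[j]}\,\beta_{c[j]}\,\mathrm{cover}_{c,i}$$

Individual coefficients come from population hyperdistributions
$\beta_j \sim N(\mu_\beta, \tau_\beta)$; the five land-cover coefficients
are jointly multivariate normal with a Wishart-prior precision matrix
(scale $I_5$, 6 degrees of freedom — with an identity scale the scale
vs inverse-scale conventions coincide numerically, and we pin "scale =
identity" for non-identity configurations). The presence indicator
$I_{c[j]}$ multiplies absent cover types out of the likelihood, so their
coefficients are informed only by the hyperdistribution. Hyperpriors:
$N(0, \text{precision } 0.01)$ for every mean; Uniform(0, 100) on the
intercept hyper-**sd**, transformed to precision; Uniform(0, 25) directly
on the footprint/elevation/slope hyper-**precisions** (both taken
literally, as stated). The footprint hyper-mean is indexed by year, giving
direct posteriors for the 2019 and 2020 population means and their
draw-wise difference. Because a population's printed mean can also be
formed by averaging individual coefficients (the two aggregations answer
slightly different questions and need not agree),
`derive_population_summaries()` exposes both, labelled `hypermean` and
`individual`.

### Sampler

The sampler is a blocked MCMC scheme written for this model:

* Each individual's 9-coefficient block is updated by **independence
  Metropolis–Hastings**. The proposal is Gaussian with precision
  $(H_j + P)/1.3$, where $H_j$ is the Bernoulli-logit curvature at a
  per-individual Laplace mode (computed once, BFGS with analytic
  gradient, weak ridge of precision 0.01 so separation cannot destroy the
  mode) and $P$ the current prior precision; its mean is the
  precision-weighted combination of the Laplace mode and the prior mean.
  At used/available data sizes the conditional posterior is close to
  Gaussian, and acceptance rates sit around 0.5–0.7. The 1.3 covariance
  inflation fattens the proposal against the logistic posterior's
  heavier-than-Gaussian tails; chains start from a proposal draw so the
  independence chain cannot begin in the proposal's far tail, and during
  burn-in only, a block with zero acceptances over 200 iterations restarts
  from its proposal (the post-burn-in kernel is untouched, so the
  stationary distribution is exact).
* All hyperparameters have **exact full-conditional draws**: conjugate
  normals for the means, truncated-gamma inversion for the uniform-prior
  precisions (the Uniform(0,100)-on-sd intercept prior transforms to a
  $\tau^{-3/2}$ density, giving a Gamma((J−1)/2, S/2) conditional truncated
  at $\tau > 100^{-2}$; the Uniform(0,25) precision priors give
  Gamma(J/2+1, S/2) truncated to (0, 25)), and a Wishart draw
  (`stats::rWishart`) with scale $(I_5 + \sum_j (\beta_j-\mu)(\beta_j-\mu)')^{-1}$
  and $6 + J$ degrees of freedom for the land-cover precision matrix.

The reference configuration is 3 chains × 30 000 iterations, burn-in 3 000,
thinning 3; retained draw counts always equal
chains × (iterations − burn-in)/thin. Because the independence-MH blocks
mix nearly as well as exact draws, far shorter runs converge in practice;
the test suite and the acceptance script use 3 chains × 3 000 (burn-in 600)
at study scale and 2 × 1 500 for replicated recovery — sizes chosen so the
split-chain Gelman–Rubin statistic comfortably meets the ≤ 1.1 rule on the
designs they run. Convergence is always computed (split-chain, every
monitored parameter: hyper-means, precisions, the land-cover precision
diagonal and every individual coefficient); a failing fit is returned with
a warning, never silently. The sampler's stationary distribution is
validated in the tests against a numerical maximum-likelihood oracle
(single individual, priors widened 100-fold, agreement within 0.05 per
coefficient) and against an independent JAGS implementation of the same
hierarchical model.

## Second-stage measurement-error models

Exposure is the arithmetic mean footprint over the available points of an
individual-year's home range — the same numbers later used as the
functional-response axis, computed once (single source of truth). The
second-stage likelihood treats the RSF posterior mean of each footprint
coefficient as observed with known precision $1/\mathrm{sd}^2$:

$$\mu_{\beta\mathrm{fp}[j]} \sim N(\beta_{\mathrm{int}[k,t]}
 + \beta_{\mathrm{slope}[\cdot,t]}\,\mathrm{exposure}_j,\;
 \tau_{\beta\mathrm{fp}[j]}),$$

with $N(0, 0.01)$ priors throughout. Structures: global (one slope per
year, intercepts by population-year), guild (slopes by guild × year, large
carnivores vs ungulates; the lone small carnivore is excluded), species
(intercept and slope per species-year). The change model regresses the
2020−2019 coefficient change on 2019 exposure with per-population
intercepts and one slope. With known observation variances these are
conjugate Gaussian linear models, so the posterior is written in closed
form and sampled exactly (independent draws) — the degenerate, zero-scan
case of a Gibbs sampler. The literal likelihood has no residual variance
beyond measurement error and can be underdispersed for real data; an
optional fixed `extra_sd` is provided (default 0, i.e. the stated model).
The change observation uses the draw-wise 2020−2019 difference when
posterior draws are available (default), falling back to
quadrature-combined sds under an independence assumption. A slope group
with fewer than two observations, or with constant exposure, is flagged
unidentifiable rather than silently shrunk to its prior.

## The synthetic generator

`generate_landscape()` builds seedable, spatially autocorrelated fields by
Gaussian-smoothing white noise (separable kernel, edge-renormalised):
elevation (and slope from its gradient), and a second field thresholded at
fixed quantiles into five land-cover classes (forest 35%, herbaceous 25%,
scrub 20%, barren 12%, water 8% — a mountain-park-like mix). Infrastructure
concentrates in a developed western sector (roads run south–north through
it, trails head east into the interior, point features cluster on roads),
so the footprint index has a strong west–east gradient and home ranges
differ widely in exposure. The park boundary is the extent inset by 4%.
Land-cover distance rasters use an exact Euclidean distance transform
(separable parabolic envelope).

`simulate_individuals()` places a disc home range per individual (same
centre both years), computes its exposure as the mean footprint over disc
cells, draws the footprint coefficient from
$N(\mathrm{fr\_int}_t + \mathrm{fr\_slope}_t \cdot \mathrm{exposure},
\mathrm{sd})$ and the other coefficients from their year means, then draws
used cells by **exact categorical sampling** proportional to
$e^{\eta}$ over the disc's cells (uniform jitter within the chosen cell)
with evenly spaced timestamps (4 h default, 0.5–24 h configurable, so the
resampler is exercised). Discs rather than KUDs keep the generator's
likelihood exact. Default truth: fr_intercept (−1.5, −2.6) and fr_slope
(−1, +4) for 2019/2020 — overall avoidance, a weakly negative
functional-response slope in the open year flipping strongly positive in
the closure year — with between-individual sds of 0.5 (footprint) and 0.3
(other coefficients): effect sizes of the order reported for mammal
footprint selection in protected areas. Recovery harnesses override the
footprint truth explicitly (e.g. a −1.88 population mean with zero slope).

What the generator does **not** emulate: movement autocorrelation
(fixes are conditionally independent given the ground-truth weights),
behavioural states, migration/hibernation events (their removal is a
pluggable exclusion hook, not a fitted procedure), multi-park geometry, and
temporally varying footprint. Passing tests therefore demonstrate correct
inference under the stated model, not robustness to every property of real
telemetry.

## Numerical choices and degenerate inputs

* Bernoulli-logit log-likelihoods use the `max(η,0) + log1p(e^{-|η|})`
  form, finite to |η| = 700.
* Centring/scaling uses the n-divisor sd and refuses zero-variance
  covariates by name; scaling parameters are stored and reusable.
* Point-in-polygon treats boundaries as inside; nearest-fix resampling ties
  break to the earlier fix; equal-tailed credible intervals use the default
  type-7 quantile interpolation.
* Empty feature layers produce an `Inf` distance sentinel which decays to
  influence 0; an all-`FALSE` mask gives an all-`Inf` distance transform.
* Proposal precisions carry a 1e-10 ridge before Cholesky; truncated-gamma
  draws clamp to the nearer bound when the truncation window's mass
  underflows.

## Known limitations

* **KUD availability attenuates strong gradients at small n.** The 95% KUD
  is an estimate of the *use* distribution; when selection along a steep
  footprint gradient is strong and tracks are short, the isopleth itself
  absorbs much of the selection, and uniform-within-KUD availability leaves
  little used-vs-available contrast — fitted footprint coefficients
  attenuate toward zero. This is a property of the design, not of the
  estimator; the package's parameter-recovery checks therefore run on the
  exact-likelihood harness (`simulate_rsf_dataset()`, disc availability),
  while the KUD path is exercised end-to-end for correctness of the
  machinery. Real analyses mitigate this with longer tracking durations and
  the 1:50 availability ratio.
* Isopleth rings are treated as solid (no holes), the usual case for 95%
  contours of unimodal kernels.
* The independence-MH sampler relies on the per-individual posterior being
  near-Gaussian; with very few points per individual (tens) acceptance
  drops and longer chains are warranted — the convergence check reports
  this honestly.
* Second-stage models inherit first-stage posterior summaries rather than
  full joint draws across individuals (except the draw-wise change
  observation), the standard two-stage approximation.
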