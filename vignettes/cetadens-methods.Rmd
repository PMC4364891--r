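---
title: "Methods: hierarchical Bayesian density from dynamic topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian density from dynamic topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model, the numerical choices, and the design
decisions behind `cetadens`, in the order a maintainer is likely to
question them.

## The joint model and its assumptions

The package couples two stochastic processes observed through one survey.

**Observational process.** Perpendicular sighting distances are
half-normal, $x_j \sim N(0, \sigma_j^2)$ on $x \ge 0$. The half-normal
scale is tied to the effective strip half-width (ESW) $w$ by
$\sigma = w\sqrt{2/\pi}$: this is the unique relation under which
$\int_0^\infty \exp(-x^2/2\sigma^2)\,dx = w$, i.e. under which $w$ means
what distance sampling says it means. (The relation is sometimes typeset
ambiguously; `sigma_from_esw()` carries a unit test against numerical
quadrature.) The ESW is log-linear in Beaufort sea state and group size,
with a per-sighting residual $\varepsilon_0$; dolphin-like species use
$\ln s_j$ because their group sizes span orders of magnitude. At cell
level the same coefficients act on the effort-weighted Beaufort $B_i$ and
on the *predicted mean* group size, with a per-cell residual
$\varepsilon_1$. For dolphin-like species the cell covariate is the
log-scale mean $\mu_{(s)} + \sigma_{(s)}^2/2 = \ln\tilde S$, not
$\tilde S$ itself: the shared slope $\alpha_2$ must multiply commensurate
quantities at both levels for its posterior to be meaningful.

**Group sizes.** Whale-like: Poisson($\lambda_{(s)}$); dolphin-like:
log-normal. The arithmetic mean group size is
$\tilde S = \exp(\mu_{(s)} + \sigma_{(s)}^2/2)$ — an individuals-scale
quantity, which is what can divide an individual density. Group-size
parameters are informed by sightings only; gridding destroys group-size
variability, so cells contribute nothing to them.

**Counts and density.** Group counts per surveyed cell-year are Poisson
with mean $\lambda_i^{(n)} = 2 w_i L_i \hat d_i\, \hat g(0) / \tilde S$.
Division by mean group size is forced by dimensional analysis: $\hat d$
is individuals·km⁻², $2 w_i L_i$ is km², and $n_i$ counts groups.
$\hat g(0)$, the trackline detection probability, is a single scalar per
species with an informative Beta prior built by moment matching from a
published mean and CV (`g0_prior()`); the likelihood cannot separate it
from the density intercept, so its posterior reproduces the prior — a
property the acceptance tests assert rather than hide.

**Ecological process.** Density is log-quadratic or log-cubic in
rescaled ADT, or a $\vartheta$-weighted average of the two, with a
per-cell residual $\varepsilon_2$. ADT enters as
$(\text{ADT} - \text{reference mean})/100$; the reference mean used in a
fit is the effort-weighted mean ADT of the fitted cells (effort
weighting matches the data actually entering the likelihood) and is
stored in the fitted object, because quadratic coefficients are
meaningless without their centring constant.

## Priors

Non-informative except $g(0)$: Normal(0, 100²) on all regression
coefficients and $\mu_{(s)}$; Uniform(0, 10) on the three residual SDs
and $\sigma_{(s)}$; Uniform(0, 1000) on $\lambda_{(s)}$; Uniform(0, 1) on
$\vartheta$. At the simulated data sizes the likelihood dominates all of
these except the residual SDs, which remain weakly identified (their
posteriors are diagnostics, not estimands here).

## Zero-truncated group sizes (a deliberate deviation)

Observed groups necessarily have $s \ge 1$. Simulating whale-like group
sizes by rejection to $s \ge 1$ while fitting a plain Poisson is *not* a
negligible approximation at $\lambda \approx 1.8$: the truncated mean is
$\lambda/(1-e^{-\lambda}) \approx 2.16$, a +20% bias that moved the true
$\lambda_{(s)}$ outside its 95% credible interval in 9 of 10 pilot fits.
The fit therefore uses the zero-truncated Poisson by default
(`zero_truncated_sizes = TRUE`), restoring exact agreement between the
generator and the likelihood; the plain form remains available, and
`groupsize_loglik()` defaults to the plain pmf to keep its documented
contract. The generator's mean simulated group size is asserted against
the zero-truncated oracle mean, not against $\lambda$.

## The sampler

Inference is adaptive random-walk Metropolis-within-Gibbs, written in
C++ (Rcpp): univariate updates for the ~11–16 global parameters,
recomputing only the posterior components each parameter touches, and
elementwise updates for the three random-effect blocks, whose likelihood
is local. Proposal scales adapt toward 0.44 acceptance in batches of 50
during burn-in only (diminishing steps, frozen afterwards, so the chain
is a valid time-homogeneous Markov chain when retention starts). All
randomness flows through R's RNG: a fit is bit-reproducible given data,
configuration and seed. Component caches are refreshed every 500
iterations to stop floating-point drift; the compiled joint likelihood
is cross-checked against an independent R implementation to 1e-8 in the
test suite. Defaults follow the reference protocol: 10,000 iterations,
burn-in 2,000, thinning 10 — 800 retained draws per chain — and three
chains, treated as 800 *per chain* (the protocol's arithmetic is
unambiguous; how many chains multiply it is configurable).

Diagnostics: Gelman–Rubin $\hat R$ per parameter (classic
between/within-variance form; note it returns $\sqrt{(n-1)/n} < 1$ for
literally identical chains), batch-means MC error (50 batches), and a
non-convergence warning when any $\hat R > 1.1$. DIC uses the full joint
deviance (distances + sizes + counts) with
$p_D = \bar D - D(\text{posterior means, random effects included})$;
the observational sub-model is shared across habitat forms, so DIC
differences isolate the ecological one.

## The posterior predictive check

The Bayesian p-value draws, for every retained draw, a replicated count
vector $n^{rep} \sim \text{Pois}(\lambda^{(m)})$ and compares a
sums-of-squares discrepancy for replicate and observation; ties split
evenly. The Freeman–Tukey form $\sum_i(\sqrt{n_i} - \sqrt{\lambda_i})^2$
is the default (stable for the small counts this model produces); the
raw form $\sum_i (n_i-\lambda_i)^2$ is a configuration away, and at desk
scale the two centre in the same place.

A property of this check worth stating plainly: at desk scale
(~100–200 cells) its distribution under a correctly specified model
centres *above* 0.5. Grid-integration experiments with exact per-cell
posteriors show that conditioning through the cell random effects alone
leaves the p-value near 0.5; the upward drift comes from the posterior
adaptation of the global parameters to a small survey, and fades as data
grow — which is why a fit to a 24-year archive can report ≈0.48 while a
200-cell synthetic fit typically reports more. The test suite asserts
the calibration it can compute: the mean p-value over 20 a-priori-seeded
replicate fits lies within 0.5 ± 0.15.

## What the synthetic world is, and is not

The generator's defaults are the stated world the tests rely on:

- detection coefficients, group-size parameters, habitat slopes and
  $g(0)$ are the published posterior means for the two study species
  (blue whale: $\alpha = (1.111, -0.0081, 0.0219)$,
  $\lambda_{(s)} = 1.802$, $g(0) = 0.921$, $\omega_1 = -16.2$,
  $\omega_2 = -46.88$; dolphin: $\alpha = (0.172, -0.155, 0.274)$,
  $\tilde S = 258.7$, $g(0) = 0.970$, $\omega_1 = -10.14$,
  $\omega_2 = -28.91$);
- the density *intercepts* are raised (whale $\omega_0 = -5.0$, dolphin
  $-0.7$) because the published intercepts describe basin-wide densities
  observed over 24 survey years: at desk scale (~200 cells × ~22 km)
  they yield well under one expected sighting, and no model is fittable
  on an empty sighting table. Raised intercepts keep every slope at its
  published magnitude while giving ~100–200 sightings per survey;
- ADT fields span roughly 30–110 cm (base level 70 cm, spatial harmonic
  amplitude 28 cm, weekly AR(1) persistence 0.8, clamped to range),
  matching the span over which the habitat response is defined;
- Beaufort states 0–5 with a sea-state distribution typical of offshore
  surveys; residual SDs $\sigma_{\varepsilon_0} = \sigma_{\varepsilon_1}
  = 0.1$, $\sigma_{\varepsilon_2} = 0.2$ — modest but non-zero, so the
  hierarchy is exercised;
- transects are zig-zags chopped into ~11 km segments; total effort is
  conserved exactly. Transect placement in the real surveys followed
  stratum designs that are not reconstructable; the zig-zag is a
  stand-in with the right statistical role (cells visited irrespective
  of their ADT), not a reconstruction.

The generator makes no attempt to mimic eastern-Pacific oceanography —
no Costa Rica Dome, no Kelvin waves, no land. A green test therefore
establishes that the inference machinery recovers the statistical
structure it assumes, not that the package would reproduce any
particular published map.

## Numerical and interface choices

- Cells are half-open intervals $[x, x+1/3) \times [y, y+1/3)$; boundary
  points belong to exactly one cell. Segment lengths use the haversine
  formula; splitting at cell boundaries interpolates linearly in
  lon/lat, and sub-lengths are proportional shares of the declared
  length, so effort is conserved to machine precision.
- Cells are per-year records; a cell surveyed in several weeks gets the
  effort-weighted mean of its weekly ADT values.
- Distance truncation is off by default (no truncation distance is
  published); an optional right-truncation renormalises the half-normal.
- $\varepsilon_2$ is excluded from prediction surfaces: predictions
  convert ADT through the *parameter* posteriors, and fitted residuals
  belong to fitted cells. `include_residual = TRUE` draws fresh
  residuals for honest-width predictive bands.
- ENSO labels use ±0.5 thresholds on the July–December mean of the
  index — an implementation convenience; the index itself is continuous
  annotation and never alters a surface.
- ADT rasters and prediction surfaces are exchanged as long-format CSV
  (no NetCDF library is assumed); fitted models serialise their summary
  table, pooled draws, and a JSON metadata record.
- DIC model choice between the quadratic and cubic forms is a
  moderate-n property: in small surveys the cubic coefficient stays
  prior-dominated, contributes no effective parameter, and DIC cannot
  penalise it; the model-selection tests use ~290-cell surveys where
  $\theta_3$ is likelihood-identified.

## Known limitations

- Random-walk mixing for the residual SDs is slow; their $\hat R$ can
  exceed 1.1 on small surveys (the fit warns). The estimands the package
  is built for — detection and habitat coefficients, $g(0)$, density
  surfaces — mix well under the default protocol.
- For dolphin-like fits, $\alpha_0$ and $\alpha_2$ ride a near-collinear
  ridge (the $\ln s$ covariate varies little within a survey); their
  joint posterior is well defined but individually they are wide and
  slow to decorrelate at desk scale.
- The Poisson count assumption leans on gridding into small cells; the
  per-cell residuals absorb moderate overdispersion, which in turn makes
  the posterior predictive check insensitive to mild misspecification.
- Planar geometry inside the simulated extent; great-circle effects are
  negligible at 1/3° but the gridding module still measures real
  segment lengths with the haversine formula.
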