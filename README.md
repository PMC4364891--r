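# cetadens

Hierarchical Bayesian inference of cetacean population density from the
absolute dynamic topography (ADT) of the ocean surface.

## The problem

Line-transect surveys record where whales and dolphins were seen along a
ship's track, but raw sighting rates confound three things: how many
animals are there (the ecological signal), how far away groups can be
detected (sea state, group size), and how unevenly the ocean was surveyed.
`cetadens` fits the three processes jointly, for users who want
spatially explicit density estimates from survey data plus a single
physically meaningful habitat covariate: ADT, the height of the sea
surface above the geoid.  Low ADT indicates a shoaling or outcropping
pycnocline — upwelling, eddy activity, and hence productive foraging
habitat; high ADT indicates a deep, stratified, oligotrophic water
column.

## The model

Observational process, per sighting *j* and 1/3° grid cell *i*:

- perpendicular distances are half-normal, `x_j ~ N(0, σ_j²)` on `x ≥ 0`,
  with `σ_j = w_j·√(2/π)` so that `w_j` is the effective strip half-width
  (ESW);
- the ESW is log-linear in Beaufort sea state `b` and group size `s`:
  `w_j = exp(α₀ + α₁ b_j + α₂ s_j + ε₀)` for whale-like species
  (`ln s_j` for dolphin-like species, whose groups are large and skewed);
- group sizes are Poisson(`λ_s`) (whale-like; zero-truncated by default
  since observed groups have `s ≥ 1`) or log-normal(`μ_s, σ_s²`)
  (dolphin-like, mean group size `S̃ = exp(μ_s + σ_s²/2)`);
- group counts per surveyed cell are Poisson:
  `n_i ~ Pois(2 w_i L_i d_i ĝ(0) / S̃)`, where `L_i` is transect effort
  (km), `w_i` the cell-level ESW built from the effort-weighted Beaufort
  `B_i`, and `ĝ(0)` the probability of detecting a group on the track
  line, given an informative Beta prior moment-matched to published
  double-observer estimates (blue whale mean 0.921, CV 0.023; short-beaked
  common dolphin 0.970, 0.017).

Ecological process: density is a log-polynomial in rescaled ADT
(`(ADT − mean)/100`):

    d_i(2nd order) = exp(ω₀ + ω₁·ADT + ω₂·ADT² + ε₂)
    d_i(3rd order) = exp(θ₀ + θ₁·ADT + θ₂·ADT² + θ₃·ADT³ + ε₂)
    d_i(average)   = ϑ·d_i(2nd) + (1−ϑ)·d_i(3rd)

All residual effects `ε` are zero-mean normal random effects.  Inference
is by adaptive Metropolis-within-Gibbs MCMC (compiled, seeded,
reproducible), by default 3 chains × 10,000 iterations, burn-in 2,000,
thinning 10 (800 retained draws per chain), with Gelman–Rubin R̂,
batch-means Monte Carlo error, DIC model selection among the three
habitat forms, and a posterior predictive Bayesian p-value on the Poisson
count likelihood (Freeman–Tukey discrepancy).

Because real survey archives and altimetry cannot ship with the package,
a first-class synthetic-data module generates complete surveys with the
statistical structure the model assumes: smooth weekly ADT fields on a
1/3° grid, zig-zag transects chopped into ~11 km segments, Beaufort
states, half-normal detections, Poisson/log-normal group sizes, and
Poisson counts driven by a log-quadratic ADT response — with all latent
truths exposed for testing.

## Worked example

```r
library(cetadens)

cfg    <- sim_config("whale_like", seed = 42)   # blue-whale-like truth
field  <- simulate_adt_field(cfg)
survey <- simulate_survey(cfg, field)
survey
#> Synthetic line-transect survey (whale_like)
#>   127 cell-years, 4400 km effort, 163 sightings

fit <- cetadens(survey$cells, survey$sightings,
                species_form = "whale_like", habitat_form = "poly2",
                config = mcmc_config(seed = 7))
summary(fit)
#> Posterior parameter statistics (whale_like, poly2)
#>                mean     sd     q2.5   median    q97.5 mc_error   rhat
#> alpha0       1.1226 0.1639   0.8053   1.1195   1.4514   0.0098 1.0002
#> alpha1      -0.0511 0.0422  -0.1387  -0.0508   0.0328   0.0021 1.0019
#> alpha2       0.0841 0.0479  -0.0057   0.0840   0.1791   0.0021 0.9997
#> sigma_eps0   0.1278 0.0987   0.0166   0.0976   0.3662   0.0126 1.0745
#> sigma_eps1   0.1572 0.0931   0.0277   0.1421   0.3756   0.0110 1.0214
#> sigma_eps2   0.1689 0.0965   0.0299   0.1535   0.4030   0.0117 1.0542
#> g0           0.9209 0.0214   0.8752   0.9232   0.9570   0.0005 1.0007
#> lambda_s     2.0246 0.1260   1.7891   2.0236   2.2766   0.0028 0.9997
#> omega0      -4.7168 0.1643  -5.0540  -4.7129  -4.4088   0.0065 1.0094
#> omega1     -12.9667 1.9827 -17.5239 -12.8376  -9.4437   0.1312 1.0160
#> omega2     -36.3701 8.6294 -55.6314 -35.7474 -21.0142   0.5317 1.0082
#> DIC 1340.4 (pD 22.7), Bayesian p-value 0.7333
```

The generating truth (`α₀ = 1.111`, `α₁ = −0.008`, `α₂ = 0.022`,
`λ_s = 1.802`, `ω = (−5.0, −16.2, −46.9)`) sits inside every 95% credible
interval; `g0` reproduces its Beta prior (mean 0.921) because the
likelihood cannot separate trackline detectability from the density
intercept — the informative prior is doing exactly the work it is meant
to do.  R̂ near 1 indicates the three chains mixed.

The fitted habitat response is unimodal; its optimum and a prediction
surface with 95% credible bands:

```r
om <- apply(posterior_draws(fit)[, c("omega0", "omega1", "omega2")], 2, median)
optimum_adt(om, fit$reference_mean)
#> $scaled_optimum
#> [1] -0.1795599
#> $optimum_cm
#> [1] 54.32677        # cm of ADT at which density peaks
#> $max_density
#> [1] 0.02842789      # individuals per km^2 at the optimum

predict(fit, c(45, 55, 65, 75, 85))
#>   adt     q025   median    q975 extrapolated
#> 1  45 0.011600 0.020675 0.03509        FALSE
#> 2  55 0.021448 0.028403 0.03678        FALSE
#> 3  65 0.014396 0.018920 0.02480        FALSE
#> 4  75 0.004109 0.006167 0.00876        FALSE
#> 5  85 0.000341 0.000987 0.00212        FALSE
```

Density peaks near 54 cm of ADT and collapses by 85 cm — deep,
stratified water is predicted to hold two orders of magnitude fewer
animals than the optimum.  `plot(fit)` draws the response curve with its
credible band; `enso_yearly_surfaces()` stratifies yearly prediction maps
by the July–December mean of an ENSO index (El Niño ≥ +0.5,
La Niña ≤ −0.5).

## Acceptance script

`scripts/acceptance.R` regenerates, from scratch and at a given seed,
the quantities that can be checked against published posterior
statistics: the posterior mean of `g(0)` for a blue-whale-form fit and a
dolphin-form fit to ~200-cell synthetic surveys (each pinned to its
informative prior by construction), and the posterior predictive
Bayesian p-value of the blue-whale-form fit under correct specification.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
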