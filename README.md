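# whalessm

Switching state-space movement models and ice-habitat analysis for whale
satellite telemetry.

## What it does, and for whom

Marine movement ecologists tracking baleen whales with Argos satellite tags
face two coupled problems: the fixes are irregular in time with errors from
hundreds of metres to tens of kilometres, and the scientific quantity of
interest — when the animal is *searching* (putative foraging) rather than
*transiting* — is never observed. `whalessm` implements the standard
answer end-to-end for a campaign of tagged whales:

1. **A hierarchical two-state switching state-space model.** The process
   model is a first-difference correlated random walk: the displacement at
   each 12-h step is the previous displacement rotated by a state-specific
   mean turn angle θ and damped by a state-specific persistence γ
   (autocorrelation in speed and direction), plus per-whale Gaussian
   process noise,

   d_t = γ_b R(θ_b) d_(t−1) + ε,   b ∈ {1 = transit, 2 = search},

   with first-order Markov switching between states, shared campaign-level
   parameters (γ₁ > γ₂ enforced), a per-whale diffusivity, and Student-t
   observation errors scaled by Argos location class. Fitting is by a
   blocked Gibbs sampler (forward-filtering backward-sampling for the state
   sequences, conjugate Gaussian location updates, MCMC schedule of 2
   chains × 100,000 iterations, 50,000 burn-in, thinned to every 50th by
   default).

2. **Behavioural classification and migration statistics.** Posterior-mean
   states are labelled transit (< 1.25), uncertain, or search (> 1.75);
   search patches are runs of search locations ended by ≥ 3 consecutive
   sub-threshold locations; summaries include great-circle distances and
   speeds split at the 60°S crossing, initial trajectory classes
   (South / West across 146°E / East across 160°E), and cohort tables.

3. **A sea-ice habitat model with uncertainty propagation.** Six covariates
   at Antarctic locations (log bathymetric gradient, log chlorophyll
   climatology, √distance to the 15% ice edge, ice melt rate, ice
   concentration CV two months prior, mean concentration one month prior)
   feed a binomial GAMM with penalized-spline smooths and a whale random
   intercept, after a VIF < 3 / |r| < 0.8 collinearity screen. One hundred
   joint posterior draws of locations and states then refit the model
   (multiple imputation), and the per-covariate retention count measures
   which environmental effects survive state-space uncertainty.

A synthetic-data module generates switching-CRW tracks with Argos-class
errors, environmental raster stacks with a retreating ice edge, and
behaviour–environment couplings with known coefficients, so every stage is
testable with ground truth and no external downloads. A packaged fixture
carries a 30-whale deployment summary table used by the cohort statistics.

## Worked example

```r
library(whalessm)

## ground truth: 4 whales, 80 twelve-hour steps, transit vs search
p <- movement_params(gamma = c(0.82, 0.11), theta = c(0, pi),
                     stay_prob = c(0.9, 0.9), process_sd = 18)
tracks <- simulate_tracks(p, n_whales = 4, n_steps = 80, seed = 2)
obs <- corrupt_to_argos(tracks, obs_per_day = 6, seed = 3)

post <- fit_hssm(obs, config = mcmc_config(n_iter = 1000, burn_in = 500,
                                           thin = 5, seed = 1))
print(post)
#> Hierarchical switching state-space model posterior
#>   campaign: SYN  whales: 4  state times: 319
#>   chains: 2  retained per chain: 100
#>   gamma: 0.841 / 0.083   theta: 0.025 / 3.342 rad
#>   split-Rhat: gamma1=1.006 gamma2=0.997 theta1=1.003 theta2=1.023 (converged)
```

The posterior means sit close to the generating values: persistence 0.84 vs
0.82 in transit and 0.08 vs 0.11 in search, transit turn angles near 0 and
search turn angles near π (3.34 rad ≈ 191°, the frequent reversals that
define search). `classify_behaviour(post)` returns the per-location mean
state, modal state and transit/uncertain/search label;
`segment_search_patches()` and `summarize_movement()` turn those into patch
tables and migration statistics. The cohort table of the packaged
deployment fixture:

```r
st <- fixture_stats(load_table1_fixture())
#> mean track duration 50 +/- 35 days; 16 whales with Antarctic search;
#> 47.6% of Australian-tagged whales with temperate search;
#> longest Antarctic patch 37 days
```

`run_pipeline(pipeline_config())` executes the whole chain
(simulate → fit → classify → summarise → extract covariates → GAMM →
retention → prediction map) and writes every intermediate artifact plus a
JSON report; `inst/scripts/whalessm-pipeline.R` is a thin command-line
wrapper.

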