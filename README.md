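# hproc — horseshoe process regression

`hproc` fits a Bayesian nonparametric regression for outcomes whose mean
trajectory mixes long flat stretches with abrupt jumps — step-like biomarker
series such as basal body temperature (which spikes at ovulation and drops at
menstruation), or PSA around treatment events — when the number and location
of the jumps are unknown.  It is aimed at biostatisticians and quantitative
researchers modeling small-to-moderate longitudinal or dose-response series
with possible change points.

## The model

On the grid `t_1 < … < t_m` of unique predictor values (plus optional
augmentation points), the latent function is a cumulative sum of
horseshoe-distributed increments:

```
g(E(y_i)) = f_j = α + Σ_{k ≤ j} h_k,          x_i = t_j
h_k | τ, λ_k ~ N(0, τ² λ_k² (t_k − t_{k−1})),  h_1 ≡ 0
τ ~ C⁺(0, c),   λ_k ~ iid C⁺(0, 1),   α ~ N(a, b²)
```

The global scale τ shrinks all increments toward zero (flat stretches); each
increment's local scale λ_k has heavy enough tails to escape that shrinkage
entirely where the data demand a jump.  Outcome families: Gaussian (identity
link, residual sd σ ~ C⁺(0, s)), Bernoulli (logit), Poisson (log).
Extensions: interpolation/extrapolation at augmented gridpoints (each with
its own λ_k, contributing prior terms only), linear covariates via a partial
linear model (`g(E(y_i)) = f_j + βᵀz_i`), and draw-wise monotonicity
constraints (summing |h_k|).  Sampling is by a built-in No-U-Turn HMC
sampler over a non-centered parameterization with compiled analytic
gradients; see the methods vignette
(`vignettes/horseshoe-process-regression.Rmd`) for computational details.

## Worked example

Fit a noisy step function and inspect the posterior of the latent function:

```r
library(hproc)

spec <- scenario_spec("bigstep")           # step truth on [0, 10], noise sd 0.5
dat  <- simulate_dataset(spec, "gaussian", seed = 7)
fit  <- fit_hpr(dat, sampler = sampler_config(chains = 2, warmup = 500,
                                              sampling = 500, seed = 7))
fit
#> <hpr_fit> family = gaussian, constraint = none
#>   100 observations on 100 gridpoints (0 augmented), 0 covariates
#>   2 chains x 500 draws = 1000 retained draws; 5 divergences (0.50%)

summ <- summarize_posterior(fit)           # one row per gridpoint
head(summ, 3)
#>           t is_observed      point      lower     upper
#> 1 0.0000000        TRUE  0.5991907 -0.1835511 1.5963319
#> 2 0.1010101        TRUE -0.1682149 -0.7085223 0.3396058
#> 3 0.2020202        TRUE -0.1900607 -0.6521603 0.2706666

compute_metrics(true_function("bigstep", summ$t), summ)
#>   point_set       mad     width coverage
#> 1       all 0.1772166 0.8241143     0.94
```

The summary columns are the posterior mean of `f` at each gridpoint and the
central 95% credible band; the metrics say the fit tracks the true step
function with mean absolute error ≈ 0.18 (the steps span 0–10), bands
averaging ≈ 0.82 wide, and 94% of gridpoints covered on this replicate.
`diagnostics_report(fit)` summarizes divergences, split R-hat and effective
sample sizes.

To interpolate at unobserved predictor values, pass augmentation points:
`fit_hpr(dat, x_aug = seq(0, 10, by = 0.5))` — augmented rows appear in the
summary with `is_observed = FALSE` and appropriately wider bands.

A command-line wrapper is installed at `inst/cli/hpr`
(`hpr fit --input data.csv --outcome y --predictor x …`, `hpr simulate`,
`hpr study`).

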