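# retentionfit

Fitting parametric probability distributions to interval-censored
propagule retention-time data, and quantifying what the choice of
fitting method does to downstream dispersal-kernel estimates.

## The problem

Many plants, invertebrates and microbes disperse as dormant propagules
(seeds, spores, resting eggs) carried by animal vectors — ingested and
retained in the gut (endozoochory) or attached to fur and feathers
(epizoochory). The dispersal distance of a propagule is commonly modeled
as the product of the vector's movement rate and the retention time,

    D = V × R,

so the probability distribution of retention time R largely shapes the
dispersal kernel, in particular its long-distance tail.

Retention time is continuous, but feeding trials measure it discretely:
droppings are collected at pre-set times, so each propagule is only
known to have been released within a collection interval — the data are
**interval-censored**. Fitting a continuous distribution (lognormal,
gamma or Weibull, the standard choices for these right-skewed unimodal
curves) to such data can be done in several ways, and the most common
one — treating the interval upper bounds as exact observations — turns
out to bias the fit and, through D = V × R, the estimated kernel.

`retentionfit` implements and benchmarks five fitting methods:

| method   | data used                       | estimation                        |
|----------|---------------------------------|-----------------------------------|
| `lower`  | interval lower bounds as points | maximum likelihood on densities   |
| `mid`    | interval midpoints as points    | maximum likelihood on densities   |
| `upper`  | interval upper bounds as points | maximum likelihood on densities   |
| `cd_ml`  | the censored intervals themselves | interval-censored maximum likelihood (sum of `count · log[F(uᵢ) − F(lᵢ)]`, plus a survival term for right-censored propagules) |
| `cd_nls` | empirical cumulative proportions at interval upper bounds | non-linear least squares on the cdf |

Fit accuracy is measured by the Kolmogorov–Smirnov statistic against the
known original distribution, using the resampling protocol of
simulation studies in this area (draw N = 500 values from the fitted
distribution and take the one-sample KS statistic against the original
cdf; `ks_sampled()`), alongside a deterministic oracle (`ks_exact()`).
Simulation studies over Latin Hypercube parameter designs, sample sizes
and collection schedules are orchestrated by `run_method_comparison()`,
`run_sample_size_study()`, `run_interval_study()` and
`run_kernel_bias()`.

## Worked example

Simulate a feeding trial of 500 propagules from a known lognormal
retention distribution (median ≈ 6 h), collected every 4 h up to 52 h,
then fit it two ways and compare the implied mallard-speed kernels:

```r
library(retentionfit)

original <- retention_dist("lognormal", mu = 1.8, sigma = 0.6)
trial <- simulate_censored(original, n = 500,
                           make_scheme("regular", width = 4), seed = 42)

fit_ml <- fit_cd_ml(trial, "lognormal")
fit_up <- fit_bound_ml(trial, "lognormal", bound = "upper")
fit_ml
#> <fit_result> lognormal / cd_ml: mu_hat = 1.7851, sigma_hat = 0.58718
fit_up
#> <fit_result> lognormal / upper: mu_hat = 2.0825, sigma_hat = 0.48624

ks_sampled(fitted_dist(fit_ml), original, n = 500, seed = 1)
#> <ks_result> D = 0.03802 (sampled, n_eval = 500)
ks_sampled(fitted_dist(fit_up), original, n = 500, seed = 1)
#> <ks_result> D = 0.25269 (sampled, n_eval = 500)
```

The interval-censored fit recovers the original parameters (1.8, 0.6)
almost exactly and its KS distance (0.038) sits at the resampling noise
floor (≈ 0.039 at N = 500, i.e. indistinguishable from a perfect fit),
while the upper-bound fit shifts the location parameter by +0.28 — every
propagule is pretended to have been released at the *end* of its 4 h
interval. Propagated through a 60 km/h vector:

```r
mallard <- movement_model("fixed_speed", speed = 60)
bias_table(list(
  cd_ml = estimate_kernel(fitted_dist(fit_ml), mallard, n = 1e5, seed = 1),
  upper = estimate_kernel(fitted_dist(fit_up), mallard, n = 1e5, seed = 1)))
#>   method   pldd  mean_km median_km   q99_km bias_pldd bias_mean_km bias_median_km bias_q99_km
#> 1  cd_ml 98.453 424.7242  357.7658 1407.498        NA           NA             NA          NA
#> 2  upper 99.936 541.6515  481.6381 1497.331  1.506302     27.53017       34.62384    6.382454
```

The upper-bound method overestimates the median dispersal distance by
~35 % in this trial. (As a back-of-envelope check, a 1.3 h bias in
median retention at 60 km/h is `median_shift(1.3, 60)` = 78 km.)

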