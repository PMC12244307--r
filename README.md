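# trigrowth

Growth estimation for river fish from three independent data sources, built
around the von Bertalanffy growth model (vBGM)

```
L(t) = L∞ (1 − exp(−K (t − t0))) + ε,   ε ~ Normal(0, σ)
```

with `L∞` the mean asymptotic length (mm), `K` the Brody growth coefficient
(1/yr) and `t0` the nominal age at zero length. The package grew out of a
study of European grayling (*Thymallus thymallus*) in a large alpine river,
where three kinds of data existed for one population and no single one of
them could be trusted alone:

1. **Age-at-length** from scale readings — fitted with the classic vBGM,
   both by nonlinear least squares (`fit_vbgm_nls()`) and by a Bayesian fit
   with informative priors built from eleven published grayling studies
   (`fit_vbgm_bayes()`, `build_priors()`). Scale ageing is error-prone, and
   the frequentist fit diagnoses that honestly: age-truncated samples drive
   `L∞` to absurd values while the literature priors keep the Bayesian fit
   in the plausible range.
2. **Mark-recapture increments** from PIT-tagged fish — fitted with the
   Fabens reparameterization `L_r = L_m + (L∞ − L_m)(1 − exp(−K Δt))`,
   which needs no ages at all (`fit_fabens_nls()`, `fit_fabens_bayes()`).
3. **Length-frequency time series** from seasonal monitoring — fitted with
   ELEFAN: histogram restructuring (`restructure()`), peak scoring
   (`score_growth_curve()`), a real-coded genetic algorithm
   (`ga_optimize()`) and bootstrap percentile intervals
   (`bootstrap_elefan()`).

Because the study's raw data are not publicly deposited, the package ships
a synthetic-data module (`simulate_age_length()`, `simulate_mark_recapture()`,
`simulate_length_frequency()`, `write_fixtures()`) that emulates the study's
designs — 122 aged fish, 121 recapture pairs, a 25-event seasonal survey
with ~1,800 fish — and is itself first-class, tested code: every estimator
is validated by parameter recovery on data generated from the published
estimates.

All user-facing functions take a data frame first and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`/`plot_*()`.

## Worked example

```r
library(trigrowth)

# mark-recapture: simulate a 121-pair survey from known parameters, refit
truth <- growth_params(l_inf = 536.82, k = 0.38, sigma = 15)
pairs <- simulate_mark_recapture(truth, n = 121, seed = 1)
fit <- fit_fabens_nls(pairs)
tidy(fit)
#> # A tibble: 2 × 4
#>   term  estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 l_inf  534.     506.      568.
#> 2 k        0.384    0.330     0.441
```

The generating asymptote (536.8 mm) and growth coefficient (0.38/yr) are
recovered within a few percent and well inside the intervals; `glance(fit)`
adds the residual SD and convergence flag. The Bayesian counterpart with
literature priors and the 50,000/25,000/thin-10 MCMC schedule:

```r
bfit <- fit_fabens_bayes(pairs, build_priors(),
                         mcmc_settings(seed = 2))  # defaults: 50k/25k/10, 4 chains
tidy(bfit)[, c("term", "estimate", "conf.low", "conf.high", "rhat")]
#> # A tibble: 3 × 5
#>   term  estimate conf.low conf.high  rhat
#>   <chr>    <dbl>    <dbl>     <dbl> <dbl>
#> 1 l_inf  532.     506.      562.     1.00
#> 2 k        0.385    0.337     0.440  1.00
#> 3 sigma   15.8     13.9      18.0    1.00
```

The full five-model comparison (two vBGM fits, two Fabens fits, ELEFAN) on
simulated study-like data, with a shared zero-`t0` curve overlay:

```r
report <- run_compare(list(simulate = TRUE, seed = 1))
report$table      # one row per method: L∞, K, intervals, convergence
autoplot(report)  # the five growth curves
```

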