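---
title: "Three pathways to a growth curve: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three pathways to a growth curve: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigrowth)
```

trigrowth estimates von Bertalanffy growth parameters for a river fish
population from three kinds of field data that are routinely collected but
rarely analysed side by side: ages read from scales, length increments from
PIT-tagged and recaptured individuals, and length-frequency histograms from
long-term monitoring. Each pathway has its own failure modes; fitting all of
them to the same population — as done here for European grayling in a large
alpine river — turns growth estimation into a cross-validation exercise
rather than an act of faith in a single data source.

## The growth model

All pathways target the von Bertalanffy growth model (vBGM)

$$L(t) = L_\infty\left(1 - e^{-K (t - t_0)}\right) + \varepsilon,
  \qquad \varepsilon \sim \mathrm{Normal}(0, \sigma),$$

with $L_\infty$ the mean asymptotic length (mm), $K$ the Brody growth
coefficient (1/yr) and $t_0$ the nominal age at zero length — a
curve-shifting parameter, not a biological hatching age. Ages below $t_0$
give negative expected lengths; `vbgm_length()` returns them unclamped
because fitting code treats that region as ordinary residual territory.
Lengths are millimetres throughout; ages are decimal years with days
converted at 365.25 d/yr (the data report elapsed times both as days and as
year fractions, and this divisor reproduces both).

For mark-recapture data the Fabens reparameterization predicts recapture
length from marking length and time at liberty,

$$L_r = L_m + (L_\infty - L_m)\left(1 - e^{-K\,\Delta t}\right) + \varepsilon,$$

so individual ages are never needed. The two parameterizations describe the
same trajectory when $t_0 = 0$; the test suite checks
`fabens_expected_recapture(vbgm_length(p, t), p, dt) == vbgm_length(p, t + dt)`
to $10^{-9}$ mm across a grid. Note the interpretive difference: under
Fabens, $L_\infty$ tends toward the maximum observed length, under the
age-based vBGM it is a mean — their estimates need not coincide exactly even
on perfect data.

## Ageing scales

Two readers each age three scales per fish; `mean_age()` pools all counts
with a plain arithmetic mean (no modal-age protocol — the field protocol
specifies none), and `fractional_age()` adds the fraction of the year
elapsed since the nominal April 1 hatching date, so an autumn-caught fish
with two annuli is about 2.46 years old. Captures before April 1 count
their fraction from the previous April 1, keeping the fraction non-negative.
Cohorts are labelled by the floor of the decimal age (`0+`, `1+`, ...),
matching `cohort_summary()`. No ageing-error model is applied: reader bias
and the tendency to under-age old fish are exactly the pathologies the
cross-method comparison is meant to reveal, not to correct away.

## Frequentist fits

`fit_vbgm_nls()` and `fit_fabens_nls()` minimize the residual sum of squares
with Levenberg-Marquardt (via minpack.lm). The vBGM objective is multimodal
when old fish are scarce, so fits multi-start from
$L_\infty = 1.1 \times L_{max}$ and $K \in \{0.1, 0.3, 0.6\}$, keeping the
lowest SSE. Deliberately, no box constraints are imposed by default: when an
age-truncated sample cannot identify the asymptote, the honest answer of
least squares is a huge $L_\infty$ with a tiny $K$ and an enormous upper
confidence bound, and the package reproduces that diagnosis rather than
hiding it (a `bounded = TRUE` mode exists for production use). Convergence
uses a $10^{-8}$ relative tolerance with at most 500 iterations, and
non-convergence is flagged, never silent.

Intervals default to profile likelihood (`stats::confint` on the fitted
`nls` object) because profiles respect the strong curvature of weakly
identified fits; they fall back to Wald with a warning when profiling fails
(for instance on zero-residual data). Both methods are exposed via
`confidence_intervals()` since the choice is consequential exactly when the
fit is fragile.

## Bayesian fits

Priors come from eleven published grayling growth studies
(`grayling_prior_table()`): each parameter's prior is Normal with the column
mean and sample SD of the literature estimates (that SD across studies is
one reading of "based on the parameters of the studies"; it is the one
implemented, and `build_priors()` accepts any other table if a wider spread
is wanted). $L_\infty$ and $K$ are truncated to the positive half-line;
$t_0$ is not (the literature contains negative values). The residual SD gets
a Half-Normal(0, 50 mm) prior — weakly informative on the scale of fish
lengths; the scale is a config knob. The Fabens model has no $t_0$, so its
prior table needs no $t_0$ column.

Sampling is an in-package adaptive random-walk Metropolis: Gaussian
proposals with a diagonal scale vector multiplied by
$e^{(\text{acceptance} - 0.3)}$ every 100 burn-in iterations, then frozen so
the post-burn-in chain is a valid Markov chain. The default schedule is
50,000 iterations, 25,000 burn-in, thinning 10 — retaining exactly 2,500
draws per chain — with 4 chains started at prior means jittered by 5%.
Split-$\hat R$ and effective sample size are reported; $\hat R > 1.05$
raises a warning rather than an error, since a flagged posterior is more
useful than none. Point estimates are posterior medians with equal-tailed
95% credible intervals. Prior-check mode (no data) samples the prior itself,
which the tests exploit, and with abundant precise data the posterior
collapses onto the least-squares solution — the two sanity poles of any
Bayesian fit.

## ELEFAN

Length-frequency analysis scores how well a family of cohort curves passes
through the peaks of *restructured* histograms. The restructuring recipe,
per sampling date:

1. moving average of the counts over `ma_window = 5` bins (at the edges the
   window shrinks to the in-range bins, so uniform counts restructure to
   exactly zero);
2. raw score $c/\mathrm{MA} - 1$ where the moving average is positive, else 0;
3. isolated-peak de-emphasis: positive scores are multiplied by
   $1 - n_z/(\texttt{ma\_window} - 1)$, where $n_z$ counts zero-count
   neighbours (bins beyond the matrix edge count as zero). A fully isolated
   single-bin spike is therefore zeroed entirely — a stray single old fish
   should not steer the fit;
4. negatives are rescaled so each date's scores sum to zero, then floored at
   −1. (If the rescale factor exceeds one, flooring can in principle break
   the exact zero sum; on realistic histograms the raw scores are already
   ≥ −1 and the factor is ≤ 1.)

A candidate $(L_\infty, K, t_\mathrm{anchor})$ defines one curve per birth
year in the survey span, all anchored at calendar time
$\text{year} + t_\mathrm{anchor}$. Each curve's predicted length at each
sampling date is discretized to the bin resolution — the same measurement
operator applied to the fish, which are recorded to the closest centimetre —
before the bin lookup; without this, recorded lengths (exact multiples of
the bin width) sit on bin lower edges and every curve would need to run half
a bin high. A *peak* is a maximal run of positive bins within a date, valued
at its best score; ASP sums all peak values, ESP adds each hit peak's value
once (however many curves cross it) plus the scores of crossed trough
cells, and the fitness is $R_n = 10^{ESP/ASP}/10$, so $R_n = 1$ means every
peak crossed and no trough. An exhaustive loop-based traversal oracle in the
test suite verifies this scoring on random small matrices.

The genetic algorithm is real-coded with binary tournament selection,
BLX-0.5 blend crossover (probability 0.8), Gaussian mutation (probability
0.1 per gene, SD 10% of the search range, reflected into bounds), elitism of
one, a Latin-hypercube initial population and one random immigrant per
generation; population 50 and 100 generations by default. Search bounds are
$L_\infty \in (0.8, 1.5) \times L_{max}$, $K \in (0.01, 1)$,
$t_\mathrm{anchor} \in [0, 1)$. Seeded runs are bit-reproducible and the
best fitness is non-decreasing by construction.

`bootstrap_elefan()` resamples fish (not bins) within each sampling date,
rebins, and reruns the GA per replicate; intervals are 95% percentiles.
Replicates with no peaks are dropped with a warning, and more than 20%
drops is an error. Interpretation note: the $R_n$ surface has a strongly
correlated $L_\infty$–$K$ ridge, so replicate fits scatter along that ridge
even when resampling changes the histogram imperceptibly. Bootstrap
intervals therefore quantify *estimator* uncertainty including optimizer
variation — they are not expected to collapse on near-deterministic data,
and the percentile bounds are expanded to include the point estimate in the
rare unstable case.

## The synthetic survey

The study's raw data are not deposited, so the package generates datasets
with the statistical structure its estimators assume. The generator
defaults emulate the published study conditions:

- **Age-at-length** (`simulate_age_length()`): 122 fish, integer ages 0–7
  weighted by a truncated-geometric cohort decay (ratio 0.6 — most fish aged
  0–3), an autumn capture date supplying the April-1 year fraction, and
  Normal(0, 35 mm) length noise truncated positive. The 35 mm residual SD is
  not reported anywhere; it was chosen once to reproduce the wide published
  per-cohort length ranges (~200 mm at ages 2–3) and is a parameter, not an
  assertion.
- **Mark-recapture** (`simulate_mark_recapture()`): 121 pairs, marking
  lengths uniform on 119–503 mm (truncated below $L_\infty$), times at
  liberty uniform on 0.09–1.01 yr, recapture noise SD 15 mm.
- **Length-frequency** (`simulate_length_frequency()`): 25 sampling events
  from autumn 2013 to spring 2022 (spring/summer/autumn in most years,
  winter in 2019 and 2021, only summer in 2020 — the published calendar,
  with one of the four 2021 seasons omitted to land on exactly 25 events);
  one cohort per birth year hatched April 1; within-cohort length SD of 7%
  of the cohort mean (floor 5 mm), the proportional spread typical of
  salmonid length-at-age; annual survival 0.5; recruitment of 650
  age-0 fish per cohort with a per-event catchability of 0.25, sized so the
  default survey yields on the order of 1,800 fish; optional ascending
  logistic gear selectivity (50% retention at 80 mm), on by default, so
  small young-of-year are under-represented as they are in electrofishing
  catches. Lengths are recorded to the nearest centimetre; datasets 1–2 to
  the nearest millimetre.

What the generator does *not* emulate: ageing error (scale ages are taken
as true), individual growth heterogeneity beyond the within-cohort SD, tag
loss, movement, year-class strength variation, and seasonal growth
oscillation. Passing recovery tests on these data therefore show that the
estimators are correctly implemented and statistically consistent under
their own assumptions — not that any real population satisfies those
assumptions.

## Numerical and design choices

- Binning: half-open, lower-inclusive intervals $[m - w/2, m + w/2)$ with
  mids at odd multiples of $w/2$; a 154 mm fish with 10 mm bins sits in the
  bin centred at 155 mm. Default width 10 mm, the monitoring resolution.
- Units: everything internal is mm; `cm` columns in input CSVs are scaled
  on ingest.
- Problem sizes in the tests: recovery medians use 20–50 replicate surveys;
  Bayesian coverage uses 100 replicates at a shortened schedule
  (2,500/1,000/thin 2); the frequentist coverage check uses 200 replicates;
  bootstrap examples use B = 12–100 with a reduced per-replicate GA
  (population 24–30, 30–50 generations). These sizes give Monte-Carlo error
  well inside the asserted tolerances while keeping the default suite quick.
- Seeds: every stochastic function takes an explicit `seed` and restores
  the caller's RNG stream; pipelines derive per-stage sub-seeds from one
  master seed.

## Known limitations

- ELEFAN point estimates inherit the classic identifiability limits of
  length-frequency analysis: with few fish beyond ~300 mm and a slow
  generating $K$, the $L_\infty$–$K$ ridge is shallow and the $R_n$-optimal
  curve can sit 10–20% away from the generating parameters even when the
  optimizer finds the global optimum. That mirrors the published
  experience — the approach yielded the smallest growth parameters of the
  three pathways there, attributed to the scarcity of large individuals —
  and is why the bootstrap intervals, not the point fit, are the quantity
  to take seriously from this pathway.
- The Metropolis sampler is adequate for these 3–4 parameter posteriors
  (ESS of several hundred to a few thousand per fit at the default
  schedule) but is not a general-purpose engine; no NUTS, no hierarchy.
- Profile intervals can fail on degenerate fits; the Wald fallback is then
  reported and flagged.

## A worked comparison

```{r compare, eval = FALSE}
report <- run_compare(list(simulate = TRUE, seed = 1))
report$table
autoplot(report)   # the five zero-t0 growth curves overlaid
```

With the default (full) settings this runs the two nls fits, two full MCMC
schedules and the genetic algorithm; expect a few minutes. The README's
worked example shows the two Fabens fits from the same simulated survey.
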