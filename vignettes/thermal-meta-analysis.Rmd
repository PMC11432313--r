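---
title: "Methods: thermal life-history meta-analysis with fawmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal life-history meta-analysis with fawmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawmeta)
```

## The analysis model

`fawmeta` synthesises multi-study temperature-gradient rearing
experiments on the fall armyworm. Each source study rears insects at
several constant temperatures under one (relative humidity, photoperiod)
regime and reports, per trait and temperature, a mean, a dispersion (SD
or SE) and a sample size. The package's unit of analysis is the
*contrast*: a treatment temperature paired with its own study's
lowest-temperature arm, which is always the control. This within-study
pairing removes between-study level differences (lab protocol, strain,
diet) from the effect size itself.

The effect size is the log response ratio
$RR = \ln(\bar{X}_t/\bar{X}_c)$ with delta-method variance
$v = s_t^2/(n_t\bar{X}_t^2) + s_c^2/(n_c\bar{X}_c^2)$. It assumes
strictly positive, ratio-scale trait means (days, eggs, percent) and
approximately lognormal sampling error — reasonable for durations and
counts, questionable for percentages near 0 or 100 (see Limitations).
No small-sample bias correction is applied to the ratio; the plain
estimator keeps the pooled value interpretable as a ratio of means.

Pooling is inverse-variance weighting under either a common-effect
(fixed) model or a random-effects model whose between-effect variance
$\tau^2$ is estimated by restricted maximum likelihood. The 95%
interval uses the 1.96 normal quantile without a Knapp–Hartung
adjustment; with the dozens-to-hundreds of effects typical here the
difference is negligible, and the plain normal interval keeps the
closed forms exactly testable. Cochran's $Q$ and $I^2$ always use
fixed-effects weights, the scale on which the homogeneity chi-square is
defined.

## Moderators and the heterogeneity partition

Relative humidity (percent) and photoperiod (hours of light per 24 h,
parsed from `L:D = h:h` strings) moderate the temperature response.
Meta-regression is run one moderator at a time by default — matching how
separate humidity and photoperiod tests are usually reported in this
literature — with a joint design available by passing several moderator
names at once.

Two weighting schemes coexist deliberately:

* the partition $Q_t = Q_m + Q_e$ is computed under **fixed-effects
  weights**, where it is an exact algebraic identity (model and
  residual weighted sums of squares of a weighted least-squares fit
  with an intercept); the package tests it to $10^{-8}$;
* coefficient estimates and standard errors are reported from the
  **REML-weighted** fit, the appropriate inferential model when
  residual heterogeneity exists.

Moderator models only run when heterogeneity warrants them: the gate is
$I^2 > 75\%$ (strict), the conventional "high heterogeneity" threshold,
configurable via `i2_threshold`. Records with missing moderators stay
in the pooled analyses and drop out only of moderator designs.

## Temperature profiles and optimal conditions

Treating temperature as continuous, `temperature_profile()` pools
effects within each treatment temperature and fits a weighted quadratic
in temperature (REML weights). The optimum is the vertex
$-\beta_1/(2\beta_2)$, clamped to the observed range; profiles whose
curvature points the wrong way, or whose vertex falls outside the
observed temperatures, are flagged monotone and report the best
endpoint. A quadratic rather than a smoother keeps the optimum a
deterministic, testable closed form.

`optimal_conditions()` defines a trait's optimal environment as the
observed (temperature, humidity, photoperiod) cell whose fixed-effects
pooled effect is most extreme in the trait's beneficial direction:
most negative for duration traits (fastest development), most positive
for quantity traits. This argmin/argmax-over-observed-cells construction
is an operational definition — no interpolation or response-surface
fitting between cells is attempted — and ties break toward the lower
temperature, a conservative choice in a warming-risk context. Whether
longer adult life should count as "beneficial" is genuinely ambiguous
(warm-reared adults may live shorter but reproduce faster), so
`direction_map()`'s default for adult longevity (`maximize_quantity`)
can be overridden per call.

## Publication-bias diagnostics

The funnel export gives per-effect (rr, se, precision). The asymmetry
test is Egger's regression — standardised effect on precision, normal z
test on the intercept — the standard choice when only a z and p are to
be reported. The fail-safe number is Rosenthal's: the smallest integer
$N$ of hypothetical null studies for which
$|\sum z_i|/\sqrt{k+N}$ drops *strictly below* the one-tailed critical
value (default `qnorm(0.95)`). At the exact boundary the strict
inequality matters: the package always agrees with the brute-force
"add null studies until non-significant" oracle, and the critical value
can be set to the rounded 1.645 for textbook comparability.

## Data handling rules

* SE-to-SD conversion is $SD = SE\sqrt{n}$, the inverse of
  $SE = SD/\sqrt{n}$. (Write-ups occasionally describe this conversion
  as a division by $\sqrt{n}$; that direction would shrink an SE a
  second time and is not a recognised conversion.)
* Rows reporting neither SD nor SE are imputed $SD = \bar{X}/10$ — a
  10% coefficient of variation — switchable off, in which case such
  rows are dropped with a warning.
* Exact zero sampling variances (both SDs zero) are floored at
  $10^{-8}$ with a warning and a flag, keeping weights finite while
  making the anomaly visible.
* Ties at a study's minimum temperature resolve to the first row in
  file order, with a warning, so pairing stays deterministic.

## The synthetic generator

`synthetic_config()` encodes the study conditions the package is
validated under: 20 studies, temperatures 18–36 °C in 3 °C steps with
18 °C as every study's control, sample sizes uniform on 20–60, a 10%
within-observation coefficient of variation (scaled by $1/\sqrt{n}$ for
the mean), and between-study variance $\tau^2 = 0.04$ on the log scale
— a realistic magnitude for log-ratio effects in insect rearing
studies. Duration traits follow the minimal entomological degree-day
model, duration $= K/(T - T_0)$ with $K = 270$ degree-days above
$T_0 = 12$ °C, producing the monotone decrease in development time seen
across this literature; quantity traits follow a peaked log-quadratic
thermal performance curve with vertex 32 °C and width 6 °C, so their
true log response ratio is an exact quadratic in temperature. Humidity
and photoperiod act multiplicatively on the treatment response (log
slopes 0.02 per percent and 0.01 per light hour, centred at 70% and
12 h); each study's regime is assigned by cycling deterministically over
the condition pools, so the closed-form ground truth is independent of
the noise seed.

What the generator does *not* emulate: correlated effects within a
study sharing one control arm (each contrast is treated as
independent), non-constant coefficients of variation, reporting or
publication selection, temperature-dependent mortality truncating
sample sizes, and any attempt to reproduce a specific deposited
dataset's values. Passing recovery tests therefore demonstrates that
the estimators are correct under the stated model, not that real
armyworm data satisfy that model.

## Numerical choices

* REML: bounded one-dimensional maximisation of the restricted
  log-likelihood over $\tau^2 \in [0,\ 10 \cdot \mathrm{var}(rr)]$
  (`stats::optimize`, tolerance $10^{-10}$), with $\tau^2 = 0$ and the
  DerSimonian–Laird moment estimate evaluated as extra candidates so a
  boundary solution is never missed. Deterministic; validated against a
  $10^{-4}$-step grid search of an independently coded restricted
  likelihood and against `metafor::rma(method = "REML")`.
* The random-effects structure is single-level (one $\tau^2$); nesting
  effects within studies is a known extension the closed pooling
  formulas do not support, and is left out of scope.
* $I^2$ truncates at 0; degenerate designs (constant moderator,
  rank-deficient matrix, fewer effects than coefficients) error with
  the offending columns named rather than silently dropping terms.

## Validation problem sizes

The test suite validates closed forms on ≤10-effect fixtures to
$10^{-8}$; REML against the grid oracle to $10^{-3}$; type-I error of
the homogeneity and null-moderator tests on 2000 simulated homogeneous
sets ($k = 10$, acceptance band 5% ± 1.5%); CI coverage on 1000
random-effects replicates ($k = 50$, band 92–97%); and parameter
recovery (median $\hat\tau^2$ within ±50% of 0.04, median humidity
slope within ±0.005 of 0.02) on 200 replicates of a 100-study
single-trait design, with temperature entering as a factor so the
residual between-study variance equals the generator's $\tau^2$.

## Limitations

Eclosion rate is a percentage; log response ratios compress near 100%
and the generator's lognormal noise model fits it poorly. Effects
sharing a control arm are correlated, which the single-level model
ignores — pooled standard errors are mildly optimistic as a result.
Optimal-condition cells with a single effect rest on one contrast and
should be read alongside their CI and `n_cells`. The quadratic profile
is a local description of the thermal response within the observed
range, not a mechanistic performance curve.
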