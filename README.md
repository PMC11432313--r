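# fawmeta

Meta-analysis of how temperature — moderated by relative humidity and
photoperiod — shifts the life-history traits of the fall armyworm
(*Spodoptera frugiperda*), an invasive crop pest whose development rate,
fecundity and survival are tightly temperature-dependent. The package is
aimed at entomologists and ecologists synthesising multi-study
temperature-gradient rearing experiments: each source study rears insects
at several constant temperatures, and within each study the
lowest-temperature arm serves as the control against which every warmer
arm is contrasted.

## The statistics

For a treatment arm with mean $\bar{X}_t$ (SD $s_t$, $n_t$ individuals)
and its study's lowest-temperature control $\bar{X}_c$ ($s_c$, $n_c$),
the effect size is the log response ratio and its sampling variance

$$RR = \ln\!\left(\bar{X}_t/\bar{X}_c\right), \qquad
v = \frac{s_t^2}{n_t \bar{X}_t^2} + \frac{s_c^2}{n_c \bar{X}_c^2}.$$

Effects are pooled by inverse-variance weighting,
$RR^+ = \sum w_i RR_i / \sum w_i$ with $w_i = 1/v_i$ (fixed effects) or
$w_i = 1/(v_i + \tau^2)$ (random effects), standard error
$s(RR^+) = 1/\sqrt{\sum w_i}$ and 95% CI $RR^+ \pm 1.96\, s(RR^+)$. The
between-effect variance $\tau^2$ is estimated by restricted maximum
likelihood. Heterogeneity is quantified by Cochran's
$Q = \sum w_i (RR_i - RR^+)^2$ (chi-square, $k-1$ df) and
$I^2 = \max(0, (Q - df)/Q) \times 100$. When heterogeneity is high
($I^2$ above a configurable 75% gate), moderators (humidity, photoperiod,
temperature as a continuous covariate) enter a weighted meta-regression
and total heterogeneity partitions exactly as $Q_t = Q_m + Q_e$ under
fixed-effects weights. Publication bias is screened with funnel data,
Egger's regression test and Rosenthal's fail-safe N. Missing SDs may be
imputed as one tenth of the mean; reported SEs are converted via
$SD = SE\sqrt{n}$.

A synthetic-data module generates multi-study datasets with closed-form
ground truth — duration traits follow a degree-day model
$K/(T - T_0)$, quantity traits a peaked thermal performance curve — so
every stage of the pipeline can be validated by parameter recovery.

## Worked example

```r
library(fawmeta)

ds  <- synthesize_dataset(synthetic_config(n_studies = 10), seed = 42)
res <- run_pipeline(ds$observations)
print(res)
#> Fall armyworm thermal meta-analysis pipeline
#>   350 observations, 300 effects, 10 studies, 5 traits
#> random-effects pooled log response ratio (k = 300)
#>   RR+ = -0.3195  (SE 0.0771, 95% CI -0.4706 to -0.1683)
#>   Q = 1095527.4837 (df = 299, p = 0), tau^2 = 1.7831, I^2 = 99.97%
```

The negative pooled log response ratio says that, averaged over all
traits and studies, trait values at warmer temperatures are about
`exp(-0.32) ≈ 0.73` times their lowest-temperature values — development
accelerates with warming. The egg stage alone shrinks much faster:

```r
print(res$by_trait[["egg"]])
#> random-effects pooled log response ratio (k = 60)
#>   RR+ = -0.8562  (SE 0.0502, 95% CI -0.9547 to -0.7577)
#>   Q = 16264.2139 (df = 59, p = 0), tau^2 = 0.1509, I^2 = 99.64%
```

Fecundity follows a peaked thermal response; its fitted optimum recovers
the generator's true 32 °C peak:

```r
fec <- res$effects[res$effects$variable == "fecundity", ]
temperature_profile(fec, direction = "max")
#> Temperature-response profile (6 temperatures)
#>   optimum = 32.02 C (quadratic vertex, direction = max)
```

Per-trait optimal observed conditions (`optimal_table(res$effects)`)
and bias diagnostics (`res$bias`: Egger p = 0.1124, fail-safe
N = 5,934,577 here) complete the bundle, and `run_pipeline(...,
out_dir = "results")` writes every table as CSV/JSON with a run
manifest. A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/fawmeta-cli.R simulate --seed 7 --out data/
Rscript inst/scripts/fawmeta-cli.R run --input data/observations.csv --out results/
```

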