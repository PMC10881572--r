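# ofhl

Tools for the **odd Fréchet half-logistic (OFHL) distribution**, a
two-shape-parameter lifetime model for positive data whose hazard can be
decreasing, increasing, bathtub or upside-down bathtub shaped. It arises by
pushing the half-logistic CDF `M(x; θ) = (1 − e^{−θx})/(1 + e^{−θx})`
through the odd Fréchet transform `F = exp{−[(1−M)/M]^α}`, giving

    F(x; α, θ) = exp{ −g(x)^α },   g(x) = 2·e^{−θx} / (1 − e^{−θx}),
    Q(u)       = (1/θ) · log[ 1 + 2·(−log u)^{−1/α} ],

for `x > 0` and shapes `α, θ > 0`. The closed-form quantile function makes
simulation and spacings/plotting-position estimators cheap, which is the
point of the package: it is aimed at survival and reliability analysts who
want to *fit* this family by more than maximum likelihood and to *compare*
the estimators honestly.

The package provides:

* `dofhl` / `pofhl` / `qofhl` / `rofhl` / `hofhl` — density, CDF/survival,
  quantiles, inverse-transform sampling, hazard; plus moments, MGF,
  incomplete and conditional moments, mean residual life, mean waiting
  time (`ofhl_moment()` and friends — series expansion with honest
  non-convergence reporting, quadrature fallback) and extreme order
  statistics.
* `ofhl_fit()` — six classical estimators under one deterministic
  multi-start optimiser: maximum likelihood (MLE), Anderson–Darling (ADE),
  Cramér–von Mises (CVME), maximum product of spacings (MPSE), ordinary and
  weighted least squares (OLSE/WLSE).
* `ofhl_gof()` — AIC/SIC/CAIC/HQIC, both Anderson–Darling/Cramér–von Mises
  reporting conventions (direct statistics and the composite-normality
  A\*/W\* used in the comparison-table literature), the Kolmogorov–Smirnov
  test, and the total-time-on-test transform (`ttt_curve()`).
* `ofhl_sim()` — a seeded Monte-Carlo engine comparing all six estimators by
  average estimate, absolute bias, MSE and MRE with average-tie rank
  aggregation, in the published three-sets × five-sizes design.
* `ofhl_data()` — the two benchmark datasets (108 COVID-19 mortality rates
  for Mexico; 45 chemotherapy survival times), shipped as plain text.
* a thin command-line front end, `inst/cli/ofhl.R`, with verbs
  `fit`, `gof`, `simulate`, `ttt`, `fixtures`.

## Worked example

Fit the COVID-19 mortality data by maximum likelihood and compare against
the half-logistic baseline:

```r
library(ofhl)
x   <- ofhl_data("covid_mexico")
fit <- ofhl_fit(x, "mle")
fit
#> OFHL fit (MLE), n = 108
#>   alpha = 1.0084, theta = 0.2807
#>   objective = 266.453, -log L = 266.4532, converged: TRUE

ofhl_gof(x, fit)
#> Goodness of fit (n = 108, k = 2)
#>   -log L = 266.4532 | AIC 536.9064  SIC 542.2706  CAIC 537.0206  HQIC 539.0814
#>   A* 0.3623  W* 0.0623  (direct AD 0.3959, CvM 0.0699)
#>   KS 0.0696 (p = 0.6717)

fit_hl(x)
#> OFHL fit (HL-MLE), n = 108
#>   theta = 0.2540
#>   objective = 285.789, -log L = 285.7890, converged: TRUE
```

The fitted shapes `(α̂, θ̂) ≈ (1.008, 0.281)` say the data are close to the
`α = 1` sub-family with a scale of about `1/0.281 ≈ 3.6` deaths-per-day
units; the fitted mean `ofhl_moment(1, fit$alpha, fit$theta)` is 5.79 and
the fitted median 4.83, reflecting the right skew. Every information
criterion is far below the half-logistic baseline's (AIC 536.9 vs 573.6)
and the KS test does not reject (p ≈ 0.67), while it firmly rejects the
baseline — the extra shape parameter is doing real work.

The other five estimators give nearby but not identical fits
(`ofhl_fit(x, "mpse")`, etc.); `ofhl_sim()` quantifies which of them to
trust at which sample size. In the published design, MPSE and MLE lead in
MSE at essentially every cell.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the MLE shape
estimate on the COVID-19 dataset (`t1`), the MLE rate estimate on the
survival dataset (`t8`), and the Monte-Carlo MSE (`t11`) and mean absolute
bias (`t12`) of the MLE of `α` from 1000 seeded replications of size 400
drawn from truth `(α, θ) = (0.25, 0.75)`, writing one JSON object with a
`value` and problem-size `n` per quantity.
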