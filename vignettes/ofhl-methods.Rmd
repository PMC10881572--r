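---
title: "The odd Fréchet half-logistic model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The odd Fréchet half-logistic model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofhl)
```

## The model

The half-logistic (HL) distribution with CDF
$M(x;\theta) = (1-e^{-\theta x})/(1+e^{-\theta x})$ is a light-tailed
one-parameter lifetime model with monotone hazard. Pushing any baseline CDF
$M$ through the odd Fréchet transform
$F(x) = \exp\{-[(1-M)/M]^{\alpha}\}$ multiplies its flexibility: the odds
ratio $(1-M)/M$ of the HL baseline is
$g(x) = 2e^{-\theta x}/(1-e^{-\theta x})$, giving the odd Fréchet
half-logistic (OFHL) family

$$F(x;\alpha,\theta) = \exp\{-g(x)^\alpha\}, \qquad
  f(x;\alpha,\theta) = \frac{\alpha\theta\,(2e^{-\theta x})^{\alpha}}
  {(1-e^{-\theta x})^{\alpha+1}}\,e^{-g(x)^\alpha}, \qquad x > 0,$$

with two positive shape parameters. $\theta$ carries units of $1/x$ and acts
as a pure scale on the quantile function; $\alpha$ reshapes the hazard, which
can be decreasing, increasing, bathtub or upside-down bathtub shaped. The
quantile function is closed form,
$Q(u) = \theta^{-1}\log[1 + 2(-\log u)^{-1/\alpha}]$, so the median is
$Q(1/2)$ and random generation is plain inverse transform — no rejection step
is ever needed. (For $\alpha=\theta=1$ the median evaluates to
$\log(1+2/\log 2) \approx 1.35722$.)

All distribution functions run through $\log g(x) = \log 2 - \theta x -
\mathrm{log1p}(-e^{-\theta x})$ and only ever form $g^\alpha$ as
$\exp(\alpha \log g)$: this is stable both as $x\to 0^+$ (where $g$
overflows) and in the far right tail (where it underflows). `dofhl()` returns
0 and `pofhl()` its limit values for $x \le 0$, matching the usual
distribution-API conventions rather than erroring.

## The moment series and its limits

Expanding $e^{-g^\alpha}$ (Taylor) and $(1-e^{-\theta x})^{-(\alpha k +
\alpha + 1)}$ (binomial) rewrites the density as a double power series in
$e^{-\theta x}$ with coefficients
$\eta_{k,\ell} = \frac{(-1)^k}{k!}\binom{\alpha k+\alpha+\ell}{\ell}$, and
term-by-term integration yields

$$E[X^r] = \alpha \sum_{k,\ell\ge 0} \eta_{k,\ell}\,
  \frac{2^{\alpha(k+1)}}{(\alpha(k+1)+\ell)^{r+1}}\,
  \frac{\Gamma(r+1)}{\theta^r},$$

with incomplete-gamma analogues for the partial moments and the residual-life
functions. This rearrangement is **only formally convergent**: for
$\alpha(k+1) > r$ the inner $\ell$-sum diverges term-by-term (the
interchange of summation and integration is not justified), and summing $k$
first at each $\ell$ the series converges only conditionally, with peak
intermediate terms growing like $e^{c\sqrt{\ell}}$ — catastrophic
cancellation in double precision. Empirically the truncated sum (defaults
$k_{\max}=60$, $\ell_{\max}=400$, early stop when three consecutive
$\ell$-sweeps each contribute less than `rel_tol` $=10^{-10}$ of the running
total) agrees with quadrature to better than $10^{-6}$ relative for
$\alpha \lesssim 0.5$ and fails detectably beyond.

The package therefore treats the series as one *method*, not as the truth:

* `method = "series"` — the truncated double sum; budget exhaustion, overflow
  or detected cancellation (peak term magnitude swamping the total) raises an
  error of class `"ofhl_nonconvergence"` carrying the partial sum, never a
  silently wrong value;
* `method = "quadrature"` — adaptive quadrature of $x^r f(x)$;
* `method = "auto"` (default) — series first, quadrature on non-convergence.

The incomplete-gamma weights slow the inner decay further, so the
series route for partial moments typically needs a larger $\ell$ budget
(and a looser `rel_tol`, since the cancellation noise floor sits near
$10^{-9}$ relative) than the raw moments; the tests exercise this
explicitly. The MGF is the Maclaurin sum $\sum_r t^r E[X^r]/r!$; since the
density's right tail decays like $e^{-\theta\min(\alpha,1)x}$ (exponent
$\alpha\theta$ for $\alpha\le1$), arguments at or beyond
$\theta\min(\alpha,1)$ are rejected up front rather than letting the sum
wander — the source material states no radius of convergence, so this
conservative guard is the package's own choice.

Two self-consistency readings were fixed at implementation time: the
conditional moment $\Delta_r(y) = E[X^r \mid X > y]$ uses the survival
function at the conditioning point $y$ in its denominator (the only reading
compatible with the definition — the printed display carries the integration
variable there), and non-integer moment orders are out of scope
($\Gamma(r+1)$ with integer $r$, matching how the moments are used).

**Degenerate inputs.** Deep in a tail, $\varphi_1(t)/F(t)$ (mean waiting
time) or $(E[X]-\varphi_1(t))/R(t)$ (mean residual life) become ratios of
underflowing quantities: at $F(t)\sim10^{-80}$ independent quadrature errors
in numerator and denominator produce visible bias. Once $F$ (or $R$) falls
below $10^{-30}$ the package switches to the integration-by-parts forms
$\bar\pi(t) = \int_0^t F(x)/F(t)\,dx$ and $\pi(t) = \int_t^\infty
R(x)/R(t)\,dx$ with the ratios computed in log space, keeping the integrand
in $[0,1]$ and the results inside their structural bounds.

## Estimation

Six estimators share one deterministic optimiser contract. Each objective is
minimised (the mean log spacing is negated) over $(\log\alpha, \log\theta)$
from the fixed $3\times3$ start grid $\alpha_0 \in \{0.3, 1, 3\}$ crossed
with $\theta_0 \in \{0.5, 1, 2\} \cdot \hat m$, where
$\hat m = \log 3/\mathrm{median}(x)$ moment-matches $\theta$ at $\alpha=1$
(where the median is exactly $\log 3/\theta$). Each start runs a Nelder–Mead
simplex (`reltol` $10^{-10}$, 2000 iterations) refined by a BFGS step — with
the analytic score for the MLE. Fixed starts make fits reproducible;
log-parameterisation enforces positivity without constraint handling, and
the optimum is invariant to the parameterisation (tested against bounded
natural-space optimisation to $10^{-5}$).

The log-likelihood is derived directly from the density,
$L = \sum_k \log f(x_k)$, whose final term is $-\sum_k g(x_k)^\alpha$. (A
version of the likelihood with $-\alpha\sum g_k$ — the exponent dropped — is
sometimes seen in print; only the $g^\alpha$ form is the log of the stated
density, and only it reproduces the published estimates.) The analytic score
includes the corresponding $-\sum g_k^\alpha \log g_k$ term and is verified
against central finite differences at $10^{-6}$ relative accuracy.

The minimum-distance objectives use the classical forms: Anderson–Darling
$A = -n - n^{-1}\sum_k(2k-1)[\ln F(x_{(k)}) + \ln S(x_{(n+1-k)})]$,
Cramér–von Mises $C = 1/(12n) + \sum_k\{F(x_{(k)}) - (2k-1)/(2n)\}^2$,
least squares against the plotting position $k/(n+1)$ with weights 1 (OLS)
or $(n+1)^2(n+2)/[k(n-k+1)]$ — the reciprocal variance of the $k$-th uniform
order statistic — for WLS, and the mean log spacing
$M = (n+1)^{-1}\sum\log D_k$ with boundary conventions $F(x_{(0)})=0$,
$F(x_{(n+1)})=1$. Tied observations collapse a spacing to zero; those
spacings are replaced by the density surrogate $\log f$ at the tied value
(the standard Cheng–Amin adjustment — the benchmark datasets contain no
ties, so this only guards user data). The $\ln F$ and $\ln S$ terms are
evaluated in log space directly from $g^\alpha$, with a series branch for
$\ln(1-e^{-g^\alpha})$ when $g^\alpha$ underflows.

## Goodness of fit: two AD/CvM conventions

The package reports **both** of two distinct Anderson–Darling/Cramér–von
Mises conventions, because both circulate in the lifetime-distribution
literature and they answer different questions:

* `ad_stat` / `cvm_stat` — the *direct* statistics of the fitted CDF,
  identical formulas to the estimation objectives (the delegation is tested
  to machine precision). These are the statistics whose minimisation defines
  ADE and CVME, and they grow without bound for badly misspecified models.
* `a_star` / `w_star` — the *composite-normality* variants: the fitted CDF
  values are mapped to normal scores $z = \Phi^{-1}(\hat F(x))$ and the
  small-sample-modified AD/CvM normality statistics with estimated mean and
  sd are computed, i.e. $A^* = A(1 + 0.75/n + 2.25/n^2)$ and
  $W^* = W(1 + 0.5/n)$ applied to $z$. This is what standard model-comparison
  tables in this literature tabulate (it is exactly what the popular
  normality-test routines produce when handed the probability-integral
  transform). Because the location and scale of $z$ are re-estimated, this
  variant absorbs part of the misfit and stays small even for models the
  direct statistic rejects — compare the half-logistic baseline on the
  COVID-19 data: direct AD $\approx 6.47$, composite $A^* \approx 0.51$.

The Kolmogorov–Smirnov statistic is the usual two-sided
$D = \max_k\max(|k/n - F(x_{(k)})|, |(k-1)/n - F(x_{(k)})|)$; the p-value
follows the R convention — exact distribution of $D$ for $n < 100$ (no
ties), otherwise the asymptotic Kolmogorov series
$2\sum_{j\ge1}(-1)^{j-1}e^{-2j^2\lambda^2}$ truncated at $10^{-12}$,
implemented in `kolmogorov_pvalue()`. Information criteria are
AIC $= 2k - 2L$, SIC $= k\log n - 2L$, CAIC $=$ AIC $+ 2k(k+1)/(n-k-1)$ and
HQIC $= 2k\log\log n - 2L$; CAIC requires $n > k+1$ and errors otherwise.
The scaled total-time-on-test transform
$T(r/n) = [\sum_{i\le r}x_{(i)} + (n-r)x_{(r)}]/\sum_i x_{(i)}$ provides the
usual pre-fit hazard-shape diagnostic (concave = increasing hazard, convex =
decreasing, S-shaped = bathtub).

## The Monte-Carlo study

`ofhl_sim()` reproduces the estimator-comparison design: for each cell
(parameter set $\times$ sample size), seeded samples are drawn by inverse
transform and **all requested methods are fitted to the same samples** — a
paired design, which is what makes the per-cell rankings meaningful. The
default specification mirrors the published study: 1000 replications of
sizes 20, 40, 100, 200, 400 from Set I $(\alpha,\theta)=(0.25,0.75)$,
Set II $(1.50,0.50)$ and Set III $(1.25,1.25)$. Set III is stated
inconsistently in the source (text $(1.25,1.75)$, table caption and average
estimates $(1.25,1.25)$); the default follows the table, which the printed
averages make unambiguous. A `scale` argument divides the replication count
for constrained environments; the full default study is roughly 90,000 fits
(~35 minutes on one CPU), so the test suite exercises scaled cells only.

Summaries per cell, method and parameter are the mean estimate (AVE), the
**mean absolute deviation** as Bias, the mean squared deviation (MSE) and
MRE $=$ Bias$/\vartheta$. The absolute-deviation reading is deliberate: in
the published tables every bias entry is positive even for methods whose
average estimate sits below the truth, which is only consistent with mean
absolute error. Methods are ranked ascending within each metric row with
average ranks for ties (so each row's ranks over $m$ methods sum to
$m(m+1)/2$), then summed per cell and overall.

Per-replication seeds are drawn once from the master seed
(`sample.int` after `set.seed(seed)`), so a study is byte-identical on
rerun; failed fits (none observed in practice) would be excluded per method
with counts reported, and any cell with more than 20% failures is flagged
rather than fatal.

**What the generator does and does not emulate.** Draws are exact i.i.d.
OFHL variates — the stated world of the simulation study. Green simulation
tests therefore establish correctness of the estimators *under the model*:
consistency, the bias/MSE decay, and the method ordering. They say nothing
about robustness to censoring, contamination, dependence or measurement
rounding, none of which the design includes; the two real datasets are the
only contact with data the model did not generate.

## Benchmark datasets

Two published datasets ship as plain text: 108 daily COVID-19 mortality
rates for Mexico (4 March – 20 July 2020) and survival times of
chemotherapy-treated patients. The survival source text says 46 patients but
prints 45 values; the package ships the printed 45, and the published fits
(MLE $(0.4835, 1.7273)$, $-L = 56.8353$, CVME $\hat\theta = 1.8668$, HL
$\hat\theta = 1.0012$) all reproduce from them to the printed precision, so
the 46 is evidently a typo in the prose, not a missing value. One printed
cell resists reproduction: the KS statistic of the COVID-19 MLE row. The
computed two-sided statistic is 0.0695 (identical to the reference
implementation, and every *other* printed KS cell across both datasets and
all six methods reproduces to $10^{-4}$); the printed 0.0659 — whose
companion p-value 0.7316 is exactly the asymptotic p of 0.0659 — is best
explained as a transposed-digit typo. The corresponding acceptance check is
kept at the printed value and fails honestly.

## Known limitations

* No censoring support; the likelihood is for complete samples.
* No standard errors or confidence intervals for the estimators (the source
  design compares point estimates only).
* Moment orders are positive integers.
* The moment series is a faithful implementation of a formally divergent
  expansion; for $\alpha \gtrsim 0.5$ only the quadrature route returns
  values, and the series route reports non-convergence.
* Competitor HL extensions (Kumaraswamy, exponentiated, Marshall–Olkin,
  power half-logistic) are out of scope; the baseline HL is the only
  comparison model built in.
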