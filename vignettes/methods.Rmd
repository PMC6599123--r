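---
title: "Methods: comparing exponential-model and z-score growth velocity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing exponential-model and z-score growth velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neogrowth)
```

## The two velocity metrics

For an infant with birth weight $W_1$ g, discharge weight $W_n$ g and a stay
of $D$ days, the exponential model assumes weight grows by a constant
fraction of itself per day, giving the average rate

$$\mathrm{EM} = \frac{1000 \, \ln(W_n / W_1)}{D} \quad \text{g/kg/d}.$$

The z-score metric references each weight to a sex-specific LMS growth
chart. At a given postmenstrual age (PMA) the reference distribution is
summarised by a Box–Cox power $L$, median $M$ and coefficient of variation
$S$, and

$$z = \frac{(x/M)^L - 1}{L\,S} \;(L \neq 0), \qquad
  z = \frac{\ln(x/M)}{S} \;(L = 0).$$

The ZS velocity is $z_\text{discharge} - z_\text{birth}$, with the birth
z-score taken at PMA = gestational age and the discharge z-score at PMA =
gestational age + stay. That is the only consistent way to use a fetal
reference at both time points, and `cohort_velocities()` hard-codes it.

## Calibration and agreement

EM is in g/kg/d, ZS in z-units, so they cannot be differenced directly. The
package fits the prediction regression
$\mathrm{EM} = a + b\,\mathrm{ZS} + \varepsilon$ by ordinary least squares
and analyses the per-infant difference
$d_i = \mathrm{EM}_i - (a + b\,\mathrm{ZS}_i)$, i.e. the OLS residual on the
calibration sample. The intercept is included deliberately: it makes
$\bar d = 0$ an exact identity, so every reported disagreement is purely a
ranking/shape discrepancy, not a units offset.

Agreement is summarised Bland–Altman style: $\bar d \pm 1.96\,s_d$ with the
sample standard deviation ($n-1$ denominator, the Bland–Altman convention),
plus skewness and excess kurtosis of $d$ as the normality check (an optional
Shapiro–Wilk test is available for $n \le 5000$). Each infant is classed by
$|d|$: **fair** on $[0, 2)$, **poor** on $[2, 4)$, **disagreement** on
$[4, \infty)$ g/kg/d. The half-open boundaries are a measure-zero choice
that cannot move proportions materially; the thresholds are clinically
motivated but arbitrary, and `run_pipeline(..., thresholds =)` makes them
configurable.

Determinants of disagreement are estimated by multivariable OLS of $d$ on
sex, gestational-age stratum (23–26, 27–28, 29–30, 31–32 completed weeks)
and birth-weight z-score stratum ($<-2$, $[-2,-1)$, $[-1,0)$, $\ge 0$), with
treatment coding and reference levels male / 31–32 wk / $\ge 0$, on complete
cases. 95% confidence intervals use $t_{0.975,\,n-p}$. Because "variable X
explains f% of the variance" is ambiguous when covariates are correlated,
`variance_explained()` reports both the univariate $R^2$ of the variable
alone and the incremental $R^2$ when the variable is added last; the two
coincide only under orthogonality.

## The synthetic reference chart

`synthetic_chart()` builds a weekly grid, 22–44 wk PMA, both sexes, with
constant $S$ and $L$ and a median curve

$$\log M(t) = \log M_{23} + \log(1+g)\,(t-23) - \tfrac{\rho}{2}(t-23)^2,$$

i.e. a weekly log-growth rate $\log(1+g) - \rho\,(t-23)$ that declines
linearly with age, as fetal fractional growth does; $\rho = 0$ recovers a
strictly geometric curve $M_{23}(1+g)^{t-23}$. The decline term is essential
and worth explaining. If the median grows geometrically (constant weekly
fraction), then for any infant the chart contribution to EM,
$1000\ln(M(t_d)/M(t_b))/D$, is the same constant for everyone, and EM and ZS
become structurally locked up to slope heterogeneity: simulated cohorts show
near-perfect agreement and no gestational-age effect, unlike any real
chart. With $\rho > 0$ the chart contribution depends on the ages spanned,
so less mature infants (who traverse the fast-growth region) acquire EM
velocities systematically above what their z-score change predicts — the
mechanism that generates a maturity gradient in $d$ at the weight level.

Defaults: $S = 0.13$, $L = 1$, male–female gap 4% of $M$, $\rho = 0.005$
per week, $g = 0.1617$ and $M_{23} = 521$ g. The last two were solved once,
by simulation at $n = 2 \times 10^5$, so that the default cohort's median
birth weight is 1320 g and its median EM velocity 11.4 g/kg/d — the
population anchors the generator is designed to emulate; they are fixed
constants, not fitted at run time. The resulting $M_{23}$ sits below
published preterm references because a single linear decline cannot match a
real chart's curvature everywhere; the chart is a smooth synthetic stand-in,
not a reproduction of any published table.

## The synthetic cohort

`synthetic_cohort()` draws, per infant: a gestational-age stratum with
shares 7.1 / 17.3 / 26.3 / 49.3% (GA uniform by day within the stratum), sex
male with probability 0.531, birth z-score $\mathcal N(-0.45,\,0.9^2)$,
discharge PMA $\mathcal N(38,\,1.5^2)$ weeks truncated to at least 7 days
after birth and to the chart range (resampling, with a hard error if
infeasible), and a z-score decline $\max(0, \mathcal N(0.7,\,0.4^2))$ — the
truncation encodes that essentially no very preterm infant gains z-score
over the stay; set `z_drop_sd = 0` or the mean to 0 to switch the behaviour
off. Weights are obtained by *inverting* the chart at the sampled z-scores,
which guarantees that z-scoring the cohort against the same chart returns
the sampled values exactly — the consistency property a real chart/cohort
pair cannot give a test suite. Weights are kept at full precision (a real
scale rounds to 1 g) so this round trip holds to $10^{-6}$.

All draws come from R's RNG seeded once from the config; a fixed config is
byte-reproducible, including the written CSV.

## Pair-level simulation and the residual-scale knob

One generator parameter, `em_zs_noise_sd`, deserves its own section. Both
velocity metrics are deterministic functions of the same
$(W_1, W_n, D, \text{GA}, \text{sex})$. A first-order calculation shows that
any perturbation of a weight moves EM by $1000\,\delta\!\ln W/D$ and the
predicted EM by $b \cdot \delta z \approx (1000\,S/D) \cdot \delta\!\ln W/S$
— the same amount. Weight-level noise is therefore absorbed almost entirely
by the calibration, and *no* weight-table generator using a single
consistent chart can realise an independent residual scale between the
metrics. For that reason the cohort generator is noise-free, and the
configured residual scale is carried by `simulate_velocity_pairs()`, which
draws the metric pair directly:

$$\mathrm{EM}_i = a + b\,\mathrm{ZS}_i + \beta_{\text{GA}(i)} +
  \beta_{\text{sex}(i)} + \beta_{\text{bwz}(i)} +
  \mathcal N(0, \sigma^2),$$

with $\sigma$ = `em_zs_noise_sd`. With all group effects zeroed, the sd of
the differences from `gv_agreement()` estimates $\sigma$ directly, which is
the package's parameter-recovery test. Defaults: calibration slope
$b = 2.4$ g/kg/d per z-unit and centre 11.4 g/kg/d (consistent with the
weight-level structure, where the local slope is $\approx 1000 S/D$); ZS
centred at $-0.7$ with sd 0.667; group effects 3.53 / 2.76 / 1.72 / 0 g/kg/d
by GA stratum, 0.22 for female sex, 5.09 / 3.02 / 1.10 / 0 by birth-weight-z
stratum — the magnitudes of the determinant structure the package is built
to detect; and $\sigma = 1.0$, chosen so that the total difference sd
implied by the defaults (group-effect variance plus $\sigma^2$) is about
2.1 g/kg/d, the scale of disagreement the analysis is designed around.

What the two generators deliberately do not emulate: real charts'
age-varying $S$ and $L$ (a major extra source of slope heterogeneity),
correlation between gestational age and birth z-score, morbidity-driven
growth faltering, missing data, and measurement rounding. Passing tests on
synthetic cohorts therefore demonstrate the correctness and calibration of
the *machinery*, not the numerical agreement level of any particular
clinical population.

## Numerical choices

- $|L| < 10^{-12}$ switches the LMS transform to its logarithmic limit; the
  suite checks continuity across the switch at $10^{-6}$.
- Chart interpolation is linear in each of L, M, S between grid rows —
  simple, monotone, and standard chart-tool practice; queries outside the
  grid raise an error naming the valid span rather than extrapolating.
- Chart ages are stored in whole days (weekly tables convert as
  `round(pma_weeks * 7)`, round-half-even); cohort ages are queried at day
  resolution.
- Quantiles everywhere use the linear-interpolation convention
  (`stats::quantile` type 7).
- Singular determinant designs are an error naming the collinear columns; a
  factor observed at a single level contributes no column instead of
  breaking the fit.
- `run_pipeline()` fixes every numeric to 10 significant digits before
  writing, so identical inputs give byte-identical reports.

## Problem sizes

The default study size is $n = 3954$ infants. The test suite exercises the
pipeline at $n$ between 120 and 4000 (parameter-recovery checks use
$n = 4000$ over three seeds; the stratum goodness-of-fit check uses
$n = 10^4$), which keeps the full suite in the tens of seconds while leaving
sampling error well inside the asserted tolerances.

## Known limitations

- Only weight velocity from two time points is covered: no daily
  trajectories, length or head circumference, and no multi-segment Patel
  variants.
- The shipped determinant model uses the three stratum covariates; a richer
  clinical covariate set (steroids, BPD, feeding, socioeconomic level, ...)
  can be passed through `difference_determinants(terms = )` if the cohort
  table carries the columns, but no imputation is offered — analysis is
  complete-case.
- No confidence intervals around the limits of agreement.
- Published LMS tables (Fenton 2013, Olsen) are supported through the chart
  CSV format but not redistributed with the package.
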