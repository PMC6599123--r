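# neogrowth

Weight-gain velocity of preterm infants over the neonatal hospital stay is
reported with two different metrics, and they do not always tell the same
story:

- **EM velocity** — the exponential-model rate in g/kg/d, computed from the
  birth weight `W1`, the discharge weight `Wn` and the stay length `D` days:

  `EM = 1000 · ln(Wn / W1) / D`

- **ZS velocity** — the change in weight z-score between birth and discharge
  against a sex-specific LMS growth reference, where at each postmenstrual
  age the reference is an (L, M, S) triple and

  `z = ((x/M)^L − 1) / (L·S)` (L ≠ 0), `z = ln(x/M) / S` (L = 0).

Because the two metrics live in different units, `neogrowth` calibrates the
z-score metric into g/kg/d by ordinary least squares, `EM ~ a + b·ZS`, and
then studies the per-infant difference `d = EM − (a + b·ZS)`:
Bland–Altman 95% limits of agreement (`mean(d) ± 1.96·sd(d)`), a tiered
classification (|d| < 2 g/kg/d *fair*, 2 ≤ |d| < 4 *poor*, |d| ≥ 4
*disagreement*), and a multivariable regression of `d` on infant
characteristics (sex, gestational-age stratum, birth-weight z-score stratum)
with a per-variable variance-explained decomposition. It is aimed at
neonatologists and epidemiologists who need to compare growth-velocity
definitions, audit a unit's growth reporting, or plan method-comparison
analyses.

A seedable synthetic generator produces an LMS chart (smooth median curve
with age-declining fractional growth, constant S and L, a sex gap) and a
preterm cohort whose weights are built by *inverting* that chart, so the
whole pipeline is testable without clinical data; a pair-level simulator
additionally injects a configurable residual scale between the two metrics
for studying the agreement stage itself.

## Worked example

```r
library(neogrowth)

cfg    <- synthetic_config(seed = 1, n = 1000)
chart  <- synthetic_chart(cfg)
cohort <- synthetic_cohort(cfg, chart)

res <- cohort_velocities(cohort, chart)   # EM + z-scores per infant
fit <- gv_agreement(res)                  # calibration + agreement
fit
#> Growth-velocity method comparison (n = 1000)
#> Calibration: EM = 13.641 +3.420 * ZS   (R^2 = 0.375)
#> Differences: mean -0.00, sd 1.68 g/kg/d; 95% LoA [-3.28, 3.28]
#> Agreement (|d| < 2 / < 4 g/kg/d): fair 84.8%, poor 13.1%, disagreement 2.1%

subgroup_differences(fit, "ga_stratum")
#>   group   n  mean   sd   q25 median   q75
#> 1 23-26  81  3.08 1.01  2.31   3.08  3.73
#> 2 27-28 160  1.46 0.69  1.11   1.44  1.87
#> 3 29-30 249  0.31 0.64 -0.05   0.34  0.73
#> 4 31-32 510 -1.10 1.25 -1.41  -0.93 -0.46
```

Reading: the calibration line converts each infant's z-score change into the
EM velocity it predicts; the residual `d` is that infant's method
disagreement in g/kg/d. Here 84.8% of infants fall within ±2 g/kg/d, and the
mean disagreement declines monotonically with maturity at birth — the least
mature infants (23–26 wk) show EM velocities about 3 g/kg/d above what their
z-score change predicts, because fractional fetal growth (which the chart's
median encodes) is fastest at low postmenstrual age. The determinant
regression quantifies the same structure with confidence intervals:

```r
difference_determinants(fit)
#> Determinants of the EM-ZS method difference (n = 1000)
#>   (Intercept)                -0.69 [ -0.82,  -0.55]  p <0.001
#>   sex = female               -0.04 [ -0.16,   0.08]  p 0.54
#>   ga_stratum = 23-26          4.21 [  3.98,   4.43]  p <0.001
#>   ga_stratum = 27-28          2.56 [  2.39,   2.73]  p <0.001
#>   ga_stratum = 29-30          1.43 [  1.28,   1.57]  p <0.001
#>   ...
#> Model R^2 = 0.671
#> Variance explained (univariate / added-last):
#>   sex          0.0% / 0.0%
#>   ga_stratum   62.4% / 62.8%
```

`run_pipeline(cohort, chart, out_dir = "out")` does all of the above in one
call and writes a deterministic `report.json` plus a per-infant
`scatter.csv` (`id,em,predicted_em,diff,class`) for plotting. Real data come
in through `read_cohort()` (CSV:
`id,sex,ga_days,birth_weight,discharge_weight,stay_days[,covariates]`) and
`read_growth_chart()` (CSV: `sex,pma_weeks,L,M,S`), so any published LMS
table — e.g. Fenton 2013 or Olsen — can be supplied as the reference.

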