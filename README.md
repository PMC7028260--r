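# remr

Dose-response meta-analysis of epidemiological studies that report relative
risks across exposure categories, built around a concrete question: how does
glycated hemoglobin (HbA1c, %) relate to the risk of atrial fibrillation
(AF), and of new-onset AF after coronary bypass surgery (POAF)?

The package is for meta-analysts working with study-level categorical data:
one row per exposure category per study, with RRs, confidence intervals,
reference-category flags, and (when published) case counts. It implements
the full pipeline such data need:

- **Per-study trend reconstruction.** Category log relative risks sharing a
  reference group are correlated; the Greenland–Longnecker estimator fits a
  per-unit slope by generalized least squares,
  `β̂ = (x'C⁻¹x)⁻¹ x'C⁻¹L`, with the covariance `C` built from fitted
  counts. Hamling pseudo-counts re-express a study's effects against a
  different reference while preserving every reported RR, CI width, and the
  crude margins.
- **Random-effects pooling.** DerSimonian–Laird:
  `τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`, pooled effect
  `Σwᵢ*yᵢ / Σwᵢ*` with `wᵢ* = 1/(seᵢ² + τ²)`, heterogeneity summarized by
  `I² = max(0, (Q − df)/Q) × 100` and classified low / moderate / high at
  50% and 75%. Subgroup pools, leave-one-out sensitivity analysis and
  Duval–Tweedie trim-and-fill included.
- **One-stage nonlinear dose-response (REMR).** All category-level effects
  enter one weighted regression on restricted-cubic-spline basis
  differences `b(dose) − b(ref dose)`, anchored at each study's own
  reference, with cluster-robust (by study) sandwich standard errors, a
  Wald nonlinearity test, curve prediction
  `RR(d) = exp(b'(B(d) − B(ref)))` with delta-method CIs, and extraction of
  the lowest dose with persistently significant risk elevation.
- **A synthetic-data generator** with known truth (linear or
  threshold-shaped log-RR curves, binomial counts, arbitrary reference
  categories, between-study heterogeneity) so every stage is testable
  without external data.

The study-level table the package was developed around (14 publications;
9 AF per-1% entries, 6 bypass-surgery entries, and all published category
rows) ships as `table1_fixture()` and as plain CSV in `inst/extdata/`.

## Worked example

```r
library(remr)
library(dplyr)

effects <- per_unit_effects(table1_fixture())

pool(filter(effects, outcome == "AF"))
#> Pooled RR (DL_random, k = 9): 1.21 [1.10, 1.34]
#>   Q = 54.78 (df = 8), I2 = 85% (high), tau2 = 0.0174, p = 0.0002

pool(filter(effects, outcome == "AF", !ami_cohort))
#> Pooled RR (DL_random, k = 8): 1.13 [1.09, 1.16]
#>   Q = 6.22 (df = 7), I2 = 0% (low), tau2 = 0.0000, p = 5.7e-12
```

Per 1% higher HbA1c the pooled AF risk rises by ~21%, but with high
heterogeneity (I² = 85%); dropping the one acute-myocardial-infarction
cohort (`ami_cohort`) removes the heterogeneity entirely and leaves a
stable 13% increase. Subgroups behave the same way:

```r
subgroup_pool(filter(effects, outcome == "AF", !ami_cohort), population)
#>   group                 k    rr ci_lower ci_upper    i2 heterogeneity
#> 1 diabetes_or_IGT       4  1.13     1.08     1.19   0   low
#> 2 no_known_diabetes     4  1.11     1.05     1.18  23.6 low
```

In bypass-surgery patients there is no per-1% association
(RR 1.01 [0.83, 1.22], I² = 79%). The nonlinear curve in subjects without
known diabetes:

```r
nonlin <- run_nonlinear_analysis()
nonlin$model
#> REMR dose-response fit: 12 observations in 4 studies
#>   knots: 4.938, 5.618, 8.4
#>   coefficients: linear = 0.1659, nonlin1 = -0.0579
#>   Wald p (nonlinearity) = 0.94
nonlin$threshold
#> [1] 7.63
autoplot(nonlin$curve)   # solid RR curve, dashed 95% CI, threshold marked
```

The curve rises monotonically; with only four contributing studies the
cluster-robust confidence band is wide mid-range, and its lower bound first
clears RR = 1 at 7.6% HbA1c. `autoplot()` methods produce forest plots for
pooled results and curve plots for dose-response fits; `tidy()` and
`glance()` return study-level and summary tibbles.

Estimator validation runs on simulated data with known truth:

```r
recovery_experiment(synthetic_config(n_studies = 10, beta = log(1.15), seed = 42),
                    reps = 300)$summary
#> coverage ≈ 0.94, bias ≈ 0
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package and the bundled study table, the
pooled per-1% relative risks and I² statistics for: the overall AF set, the
AF set without the AMI cohort, the diabetes/impaired-glucose-tolerance and
no-known-diabetes subgroups, the six-study POAF pool, and its
multivariable-adjusted subset — writing one JSON object per quantity.

## Package layout

| file | contents |
|---|---|
| `R/study_table.R` | validated study-table tibble, CSV I/O, bundled dataset |
| `R/doses.R` | category dose assignment rules |
| `R/effects.R` | CI/count conversions, Hamling pseudo-counts |
| `R/gl.R` | Greenland–Longnecker per-study trends |
| `R/pool.R` | DL pooling, heterogeneity, subgroup/LOO/trim-and-fill |
| `R/spline.R` | RCS basis, REMR fit, curve prediction, threshold |
| `R/synthetic.R` | synthetic-data generator and recovery experiments |
| `R/report.R` | linear and nonlinear analysis orchestration |

The methods vignette (`vignettes/dose-response-meta-analysis.Rmd`)
documents the models, assumptions, numerical choices and known
limitations in detail.
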