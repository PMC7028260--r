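---
title: "Dose-response meta-analysis of HbA1c and atrial fibrillation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response meta-analysis of HbA1c and atrial fibrillation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remr)
library(dplyr)
```

## The problem

Observational cohorts relate glycated hemoglobin (HbA1c, in %) to the risk
of incident atrial fibrillation (AF), or of new-onset AF after coronary
bypass surgery (POAF). Each study reports either a relative risk per 1%
increase in HbA1c, or category-specific relative risks against a
within-study reference category — different categories, different
references, different populations. `remr` implements the machinery needed
to combine such studies into per-unit pooled effects and a pooled
nonlinear dose-response curve:

1. **Dose assignment** — one exposure value per reported category.
2. **Effect reconstruction** — log relative risks and standard errors from
   printed CIs or from counts; Hamling pseudo-counts to re-express a
   study's categories against a different reference.
3. **Per-study trends** — the Greenland–Longnecker generalized
   least-squares slope from correlated category effects.
4. **Pooling** — DerSimonian–Laird random effects with heterogeneity
   statistics, subgroup, leave-one-out and trim-and-fill analyses.
5. **One-stage spline model** — robust-error meta-regression (REMR): all
   category-level effects fitted jointly on a restricted-cubic-spline
   basis with cluster-robust (by study) standard errors.

The study-level data the package was built around ship as
`table1_fixture()` and as a CSV under `inst/extdata/`.

## Models and estimators

### Effect reconstruction

A reported relative risk with a 95% interval becomes a log effect with
`se = (ln hi − ln lo) / (2 × 1.959964)`. Printed intervals that are
slightly asymmetric on the log scale (they exist in the bundled table) are
handled by the same formula — the point estimate is kept and the SE taken
from the full interval width; no re-centering. The multiplier 1.959964
(rather than 1.96) is a documented precision choice; the difference is far
below reporting precision.

Count-based effects use the cumulative-incidence risk ratio with
`se = sqrt(1/a − 1/n1 + 1/c − 1/n0)`, with a 0.5 continuity correction
added to all four cells when any cell is zero.

### Hamling pseudo-counts

Re-referencing category effects requires effective counts consistent with
every reported RR, every CI width, and the study's crude case/non-case
totals. Given the reference category's effective cases `a0` and total
`n0`, every other category's effective cells follow in closed form; the
two margin constraints then determine `(a0, n0)` by damped Newton
iteration. The constraint system can admit more than one positive root
(all of them reproduce the inputs exactly); the solver starts from a grid
of plausible reference sizes and keeps the root whose effective reference
denominator is closest to an even split of the study, which on
count-generated data recovers the generating counts themselves. Residual
tolerance is 1e-10 relative; non-convergence across all starts is an
error, not a fallback.

### Greenland–Longnecker trend

Category log effects sharing a reference are positively correlated. The
GL estimator builds an approximate covariance: reported variances on the
diagonal, and `1/a0* − 1/n0*` off the diagonal, where `a0*` is the fitted
reference case count matching the category totals, the total case count
and the reported RRs (for cumulative-incidence data this fixed-point
iteration converges essentially in one step; tolerance 1e-8, 200
iterations allowed). The per-unit slope is then GLS through the origin on
dose differences from the reference. With per-category totals unavailable
the Hamling pseudo-counts stand in; with no counts at all the fit falls
back to an independence covariance and records that in `cov_model`. With
a single non-reference category the estimator reduces exactly to
`L1/x1`, `se(L1)/|x1|`.

For the bundled real data every study prints a per-1% value, and the
pipeline prefers the reported value over a re-derived one
(`method = "reported"`); the GL path is exercised by the synthetic world
and by any input lacking per-unit effects.

### DerSimonian–Laird pooling

Classical moment-based random effects: fixed-effect weights `1/se²`,
Cochran `Q`, `τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`, random-effects
weights `1/(se² + τ²)`. `I² = max(0, (Q − df)/Q) × 100` is classified
low (< 50%), moderate (50–75%) or high (> 75%). DL was chosen over
REML/Paule–Mandel deliberately: the reference results this package
reproduces were produced with inverse-variance DL software, and matching
them requires the same estimator. The overall p-value is a normal z-test
on the pooled log effect. Strata of one publication (e.g. the diabetic
and non-diabetic arms of one cohort) enter pools as independent units.

Sensitivity machinery: `leave_one_out()` re-pools dropping each study in
turn; `trim_and_fill()` implements the iterated Duval–Tweedie R0 run
estimator with mirrored imputation. R0 is conservative by construction
(`k0 = run length − 1`): in a constructed experiment that deletes the
three largest effects from a symmetric nine-study set, the estimator
settles at 2 of the 3 suppressed studies — the tests freeze that honest
value rather than the idealized 3. Funnel plots themselves are
deliberately not produced: with fewer than ten studies per outcome they
are not interpretable, and the package's own analyses never reached that
count.

### REMR spline model

The one-stage model regresses all non-reference category log effects on
basis differences `b(dose) − b(reference dose)` with no intercept and
inverse-variance weights — each study is anchored at its own reference,
so reference categories contribute no observations. The basis is a
restricted cubic spline (k knots → k − 1 columns, linear tails,
normalized by the squared boundary-knot span). Coefficient covariance is
the cluster-robust sandwich with clusters = studies and CR1 small-sample
scaling `g/(g − 1)`; the nonlinearity test is a Wald F test of the
nonlinear coefficients with `g − 1` denominator degrees of freedom —
estimating-equation machinery, since no likelihood is defined for this
semi-parametric fit.

Curves are predicted as `exp(b'(B(d) − B(ref)))` with delta-method CIs,
anchored at RR 1 at the reference dose; the anchor shifts the curve but
not ratios between doses. `threshold_dose()` reports the smallest grid
dose above the anchor whose lower CI bound exceeds 1 *and stays above 1
through the end of the grid* — the persistence requirement exists to
ignore isolated crossings from spline wiggle. The default grid step is
0.01%.

**Knot placement.** Default: 3 knots at the 10/50/90 percentiles of the
observed category doses (Harrell's convention), each category-level
observation counted once. An alternative reading — percentiles weighted
by inverse variance — was considered and rejected: in the bundled data
one very large cohort reports narrow categories in a 0.5%-wide band, and
weighted percentiles collapse two of the three knots into that band,
wasting the spline's flexibility where the dose range has no span.
Explicit knot locations can always be supplied.

**Knots and change points.** A 3-knot restricted spline is deliberately
stiff; it cannot represent a flat-then-rising (hockey-stick) curve and
smears the rise toward the reference, which drags the detected threshold
far below a true change point. Simulation experiments that localize a
change point therefore use 5 knots at Harrell's 5-knot percentiles
(5/27.5/50/72.5/95); with 8 studies of 5,000 participants per category
the median detected threshold then falls within ±0.3% of a true 6.3%
change point, while the 3-knot default detects "significantly elevated"
almost immediately above the reference. The default stays at 3 knots
because the real categorical data carry only ~12 observations in 4
clusters and would not support 4 spline coefficients.

**Population restriction.** The nonlinear analysis refuses diabetic
populations by policy (`run_nonlinear_analysis()`): in the bundled data
only one diabetic cohort publishes usable category-level data, which
cannot identify a separate curve, and mixing it into the non-diabetic
curve would conflate populations with different baseline glycemia.

## The synthetic world

`synthetic_config()` describes the simulated world the estimators are
validated in; its defaults are the stated conditions of the real data the
package mirrors, not tuning dials:

| parameter | default | why |
|---|---|---|
| `dose_span` | 4.5–10% | the HbA1c range spanned by the real categories |
| `categories_per_study` | 3–6 | the real tables report 3–6 categories |
| `n_per_category` | 200–3,000 | real cohorts range from dozens to tens of thousands; this covers the informative middle |
| `baseline_risk` | 0.05 | cumulative AF incidence of the larger cohorts |
| `beta` | ln 1.15 | a per-1% effect of the size actually reported |
| `heterogeneity_sd` | 0.02 | mild between-study slope spread, enough to make τ² > 0 realistic |
| `change_point` | 6.3% | the threshold shape investigated |

Sampling is binomial (cases/N is what the real tables report), with Wald
CIs computed exactly as the pipeline computes them from real counts, and
each study drawing its own RNG substream from the root seed so that
adding studies never perturbs earlier ones. Risks implied above 1 are a
configuration error, not a silent truncation.

What a green simulation establishes — and what it does not: the generator
emulates the *structure* of published categorical data (arbitrary
references, heterogeneous sizes, known truth). It does not emulate
confounder adjustment (real category RRs are multivariable-adjusted;
synthetic ones are crude), exposure measurement error, person-time
(Poisson) outcome processes, or publication selection. Calibration
results (CI coverage ~0.94, Wald type-I error ~0.06 with 6 clusters)
carry the usual asymptotic caveats of cluster-robust inference with few
clusters; with between-study slope heterogeneity and only 6 clusters the
nonlinearity test over-rejects mildly (~10% at nominal 5%), a known
small-sample behaviour of sandwich estimators.

## Numerical choices

- z multiplier 1.959964 everywhere a 95% interval is built or inverted.
- Hamling: damped Newton, relative tolerance 1e-10, multi-start root
  selection as above.
- GL fitted counts: fixed point, tolerance 1e-8, max 200 iterations.
- Degenerate inputs: a single study pools to itself with Q = I² = τ² = 0;
  zero-width CIs are domain errors in pooling (se must be positive);
  all-open category sets cannot be dosed without a `fixed_width` rule and
  say so; an unexposed category with no bounds at all (the "Control" row
  of one real study) keeps an `NA` dose with a message and is excluded
  from trend fitting.
- Trim-and-fill trims at most 50 iterations; ties in deviation ranks are
  broken in input order.
- Thresholds are grid quantities; reported to the grid step (0.01% by
  default), never interpolated.

## Design decisions that were genuinely open

- **Dose for open-ended categories**: half the adjacent closed interval's
  width beyond the boundary (the convention in dose-response
  meta-analysis), configurable to a fixed width. Wide real categories
  (one study spans 6.8–11.4%) take plain midpoints with no truncation.
- **One study, several strata**: diabetic/non-diabetic arms are separate
  analyzable records; a cohort that published one pooled per-1% value
  plus two AF-type category sets keeps the pooled value on its primary
  record and the category sets as auxiliary strata, so linear pools count
  it once while the spline can use all its categories.
- **Subgroup membership is data, not inference**: the population tag of
  every record is stored explicitly in the table (and its CSV), so an
  editorial re-reading changes one file, not code.
- **Reported per-unit values take precedence** over GL re-derivation when
  both are available; the GL result remains accessible via `gl_slope()`.
- **The acute-myocardial-infarction cohort** is kept in the main AF pool
  but flagged (`ami_cohort`) for the sensitivity exclusion; it is the
  single largest source of heterogeneity in the bundled data (I² drops
  from ~85% to 0% without it).

## Worked example

```{r example, eval = FALSE}
effects <- per_unit_effects(table1_fixture())

# per-1% pooled effect on incident AF
pool(filter(effects, outcome == "AF"))

# sensitivity: drop the AMI cohort
pool(filter(effects, outcome == "AF", !ami_cohort))

# nonlinear curve in subjects without known diabetes
nonlin <- run_nonlinear_analysis()
autoplot(nonlin$curve)
nonlin$threshold
```

## Known limitations

- The overall AF pool computed from the nine bundled per-1% entries is
  RR ≈ 1.21 with I² ≈ 85%, while the published headline value is 1.16
  with I² = 52%. The discrepancy is dominated by the AMI cohort's per-1%
  entry, whose upstream derivation evidently differed from the printed
  value; the package reports its own reproducible result and the
  sensitivity analyses rather than adjusting inputs to match.
- On the bundled categorical data (4 studies, 12 observations), the
  lower CI of the fitted curve first clears RR = 1 at ≈ 7.6% HbA1c,
  above the published 6.3%: the AMI cohort's extreme top category
  (RR 29.7) leaves a large cluster residual that widens the robust CI
  exactly in the 6–7% band. The published curve's exact inputs and
  weights are not recoverable from the printed tables.
- Per-category counts are not published for the bundled studies; Hamling
  and GL count machinery is therefore validated on synthetic and
  count-generated data, and the real-data pools rest on reported per-1%
  effects.
- Odds-ratio/risk-ratio conversion is out of scope: effect measures are
  pooled as reported.
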