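---
title: "Scoring a healthy Nordic diet and modelling depressive symptoms: methods"
author: "hnds package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a healthy Nordic diet and modelling depressive symptoms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnds)
```

## The scientific problem

Diet quality is a modifiable candidate risk factor for depressive
symptoms. One way to quantify adherence to a healthy Nordic-style diet is
an a priori index adapted from the Baltic Sea Diet Score: nine components
scored from 4-day food-diary intakes, summed to a 0--25 point healthy
Nordic diet score (HNDS). This package implements that index, the 18-item
Human Population Laboratory (HPL) depression scale, and the statistical
machinery used to relate the two in a cross-sectional cohort of
middle-aged men: Quade's non-parametric ANCOVA across HNDS quartiles with
covariate adjustment, covariate-adjusted quartile means with normal-theory
intervals, a linear trend test, and quantile regression of the HPL total
on the HNDS at the 0.33 and 0.66 conditional quantiles.

Because the source cohort (an Eastern Finnish population study of men
aged 42--60 examined in 1984--1989) is not publicly available, the package
ships a synthetic-cohort generator calibrated to the cohort's printed
marginal statistics. Every analysis stage is therefore testable end to
end, with known ground truth, on data of realistic shape.

## The diet score

Each of six positive components (fruits and berries, vegetables, cereals,
low-fat milk, fish — all g/d — and the fat-quality ratio
PUFA/(SFA + TFA)) earns 0--3 points by within-cohort quartile of
consumption: 0 for the lowest quartile, 3 for the highest. Two negative
components (meat products g/d, total fat as a percentage of energy
intake, E%) score in the reverse order. Alcohol is binary: 1 point below
20 g ethanol/d, 0 at or above. The total ranges 0--25.

Quartile boundaries are a modelling decision the index definition leaves
open. We use the median-unbiased empirical quantile estimator
(`quantile(type = 8)`) at the 25th/50th/75th percentiles, with half-open
assignment: a value below Q1 is quartile 1, `[Q1, Q2)` quartile 2,
`[Q2, Q3)` quartile 3, and at or above Q3 quartile 4. Two consequences
are deliberate and tested:

* tied values always share a quartile, so group sizes are unequal when a
  component (or the integer-valued total score) takes few distinct
  values — the behaviour expected of quartile-grouped scores with a
  narrow range;
* if a component is constant in the cohort, every participant falls in
  quartile 4 (the "at or above Q3" rule): positive components then give
  everyone 3 points and negative components 0. This degenerate case is
  deterministic and documented rather than an error, because the score
  remains well defined.

Scoring is strict about completeness: any missing component raises an
error listing participant ids. Dropping incomplete records is the
pipeline's exclusion step, never a silent side effect of scoring.

## The HPL depression scale

The HPL total is the count of symptom-indicating answers over 18
dichotomous items (range 0--18); a total of 5 or more flags clinically
significant depressive symptoms. Items arrive already dichotomised — the
instrument's response-to-symptom mapping is not part of this package —
and any missing item makes the whole outcome missing, which propagates to
the exclusion step. No prorating is attempted: with no published
psychometrics for the scale, imputing items would manufacture precision.

## Quade's rank ANCOVA, adjusted means and the trend test

The HPL total is a right-skewed count, so group comparisons use Quade's
non-parametric ANCOVA in its standard form: rank the outcome across all
participants (mid-ranks for ties), rank each covariate column the same
way, regress outcome ranks on covariate ranks by least squares pooling
all groups, and compare the residuals across groups with a one-way ANOVA
F test on (k − 1, N − k) degrees of freedom. With no covariates this
reduces exactly to ANOVA on ranks, which the tests assert to machine
precision, and the statistic is invariant to strictly monotone transforms
of the outcome.

Two covariate sets mirror the cohort analysis: model 1 is age,
examination year and daily energy intake; model 2 adds leisure-time
physical activity (kJ/d), adulthood socio-economic status (points, higher
meaning lower status), smoking (never/previous/current, never as
reference) and marital status (couple/other, couple as reference).
Energy intake is held in kJ/d throughout; since ranks are
scale-invariant, the unit convention cannot affect the Quade results.

Point estimates per quartile are reported on the raw scale: ordinary
least-squares ANCOVA of the HPL total on quartile indicators plus
covariates, evaluated at the covariate sample means, with normal-theory
95% intervals. Pairing parametric means and intervals with a
non-parametric p-value mirrors how such tables are conventionally
presented; the two answers come from different models and the package
reports both rather than blending them. The extreme-quartile difference
is defined as adjusted mean of the lowest-adherence quartile minus the
highest, so a positive value means more symptoms with a poorer diet.

For the trend test no canonical method exists under the Quade framework;
our decision is to regress the Quade residuals (outcome ranks with
covariate-rank effects removed) on the integer quartile index 1--4 and
report the two-sided t test of that slope. A seeded null simulation in
the test suite checks the test's size.

Missing covariates follow the cohort's stated rules exactly: missing
leisure-time physical activity is replaced by the cohort mean of observed
values, missing marital status by the most common answer, and any other
missing covariate is an error because no rule exists for it. Imputation
counts are logged. The sensitivity arm repeats model 2 on records that
needed no imputation; with zero covariate missingness it coincides with
the primary model exactly, which is asserted in the tests.

## Quantile regression

The association need not be constant across the outcome distribution, so
the package also fits conditional-quantile regressions of the HPL total
on the HNDS with model-2 covariates at tau = 0.33 and 0.66 (the exact
printed levels, not 1/3 and 2/3), on complete cases. Coefficients
minimise the asymmetric absolute (check) loss. The fit proceeds in two
stages:

1. iteratively reweighted least squares on an eps-smoothed check loss
   (the weighted step is a majorise-minimise update, so the smoothed
   objective decreases monotonically), with the smoothing floor tightened
   from 1e-2 to 1e-6 and a relative-decrease stopping rule of 1e-9;
2. a vertex polish on the exact loss: an optimal check-loss fit
   interpolates as many observations as there are coefficients, so the
   fitter solves the interpolation through the current smallest-residual
   observations and then performs improving one-swap basis exchanges
   among near-zero-residual candidates until no exchange improves the
   objective.

The polish matters because IRLS alone approaches the minimiser slowly on
heavily tied integer outcomes like a symptom count. On small instances
the test suite verifies the result against exhaustive enumeration of all
interpolating bases — the exact global optimum — and on random instances
against 1000 coefficient perturbations.

Interval estimation uses a seeded participant-resampling (pairs)
bootstrap with B = 1000 replicates by default, percentile intervals, and
normal-approximation p-values from the bootstrap standard error. The
bootstrap is a design decision: no interval method is canonical for this
setting, so bootstrap coverage is itself checked by simulation (a
scaled-down study of 150 simulated cohorts of n = 300 with B = 100 in the
test suite, nominal 95% required to land in [90%, 98%]). Fitted quantiles
at the covariate means are compared across tau and a crossing (a lower
quantile fitted above a higher one) raises a warning, not an error.

## The synthetic cohort generator

The generator emulates the study conditions: by default 2603 men (the
post-exclusion analysis size) aged 42, 48, 54 or 60, examined 1984--1989.
One standard-normal latent diet-quality factor per man drives correlated
component intakes — log-normal for foods and nutrients (strictly
positive, right-skewed, the shape of food-diary data), logit-normal
clamped to (0, 100) for total fat E% — with positive loadings on
fruits/berries, vegetables, cereals, low-fat milk, fish and PUFA and
negative loadings on meat products, total fat, SFA, TFA and ethanol. A
depression liability equals `effect_size` times the diet factor plus
independent Gaussian noise and drives the 18 HPL items through a logistic
item model with per-item intercepts (conditionally independent items
given liability). Covariates couple to the diet factor through Gaussian
copulas, so their marginals match the configuration exactly while
smoking, low SES and unpartnered status concentrate among low-adherence
men, reproducing the usual confounding gradients. Setting
`effect_size = 0` severs the only path between diet and symptoms, which
the tests exploit as a null; direct confounder-to-liability paths are
available (`liability_confounding`) but default to zero.

All randomness derives from one master seed through named substreams
(an FNV-hash of variable name and seed), so the same configuration is
bit-reproducible and adding a new variable to the generator cannot
disturb existing columns.

Calibration constants were fitted once by simulation and then frozen in
the defaults. Three are worth recording:

* the quartile construction forces the mean of the eight quartile-scored
  components to about 1.5 points each, so the mean HNDS is structurally
  12 plus the abstainer fraction; the ethanol distribution (log-normal,
  median 8 g/d, log-SD 1.09) puts 20% of men at or above 20 g/d, giving
  the printed mean of about 12.8;
* an HNDS standard deviation near 4 requires cross-component
  correlation; shared factor loadings of 0.31 (foods, total fat) and
  0.25 (fatty acids) produce it;
* item intercepts spaced evenly from −1.26 to −4.71 with discrimination
  1.19 reproduce an HPL mean near 1.9, SD near 2.1 and a prevalence of
  totals ≥ 5 near 11%.
* the default `effect_size` of −0.10 yields covariate-adjusted
  extreme-quartile differences of roughly 0.2--0.3 HPL points at
  n = 2603 — the order of magnitude such cohort analyses report — while
  remaining small enough that single runs at moderate n are often
  non-significant, as a weak cross-sectional signal should be.

What the generator does **not** emulate: individual diary days, foods or
the nutrient-database conversion (only 4-day mean component intakes);
item-level psychometric structure beyond a single liability; age-specific
diet patterns; measurement error or misreporting in the diaries. Passing
tests therefore demonstrate that the statistical machinery is correct and
well calibrated under the assumed data-generating shape, not that the
substantive findings would replicate in new real data.

Missingness is injected separately from generation: leisure-time
physical activity cells at rate 8/2682 and marital status at 2/2682
(mirroring the imputation counts the cohort reports), and a block
mechanism at rate 79/2682 that removes a participant's whole diet block
or whole HPL block — the mechanism the exclusion step is designed to
catch, reproducing the 2682 − 79 → 2603 roster arithmetic in
expectation.

## Numerical and degenerate-input decisions

* Mid-ranks for ties everywhere ranks are used.
* A constant outcome, a single occupied quartile, or collinear ranked
  covariates abort the ANCOVA with a named diagnostic rather than
  returning fragile numbers.
* The quantile-regression design must be full column rank; tau must lie
  strictly inside (0, 1).
* Exclusions are whole-record and only for missing exposure or outcome
  blocks; covariate missingness never excludes.
* All report files are plain text (CSV, JSON, log) and contain no
  timestamps, so a rerun with the same configuration is byte-identical.

## Problem sizes used in the test suite

Simulation-based checks use sizes chosen to give comfortable Monte-Carlo
margins: marginal calibration at n = 5000, gradient monotonicity at
n = 20000, the Quade null at 1000 replications of n = 400, slope recovery
at n = 10000 with 200 bootstrap replicates, and the bootstrap-coverage
study at 150 replications of n = 300. These are the package's chosen
study sizes for verifying its own statistical properties.

## Known limitations

* On an integer-valued outcome such as a symptom count, a conditional
  quantile is a step function of the predictors; when the association is
  weak the exact check-loss optimum can be a perfectly flat slope of
  zero with a degenerate bootstrap interval. This is a property of the
  estimand on discrete data, not a convergence failure — an independent
  solver reaches the same objective — and it is most pronounced at
  lower quantiles, where the count's conditional quantile sits at 0
  or 1.
* The Quade F test's degrees of freedom follow the classical procedure,
  (k − 1, N − k); no small-sample permutation option is provided.
* Bootstrap p-values for quantile-regression coefficients use a normal
  approximation to the bootstrap distribution.
* The generator draws examination year independently of age, whereas a
  real rolling-recruitment cohort confounds the two mildly.
* Component semantics (e.g. whether cereals are restricted to whole
  grains) follow the index's prose description; absolute component
  cut-offs from the original Baltic Sea Diet Score are out of scope —
  only the within-cohort quartile variant is implemented.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(
  synthetic = synthetic_config(n_participants = 2682, seed = 1),
  bootstrap_B = 1000, seed = 1, output_dir = "hnds_results"
)
report <- run_study(cfg)
print(report)
```

The report lists exclusion counts, quartile sizes, imputation counts, a
descriptives table by quartile, Quade/adjusted-means/trend results for
both models, the complete-case sensitivity rerun and the two quantile
fits, and writes each as CSV beside a JSON metadata block carrying the
seed and a configuration fingerprint.
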