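# hnds — healthy Nordic diet score and depressive symptoms

`hnds` is an R package for nutritional-epidemiology analyses that relate
adherence to a healthy Nordic diet to depressive symptoms in a
cross-sectional cohort. It is aimed at researchers who work with a priori
diet-quality indices and skewed symptom-scale outcomes, and at anyone who
needs a fully testable re-implementation of this analysis chain without
access to restricted cohort data.

## What it computes

**Healthy Nordic diet score (HNDS, 0–25).** Nine components adapted from
the Baltic Sea Diet Score. Six positive components — fruits and berries,
vegetables, cereals, low-fat milk, fish (g/d) and the fat-quality ratio
PUFA/(SFA + TFA) — earn 0–3 points by within-cohort quartile of
consumption (lowest quartile 0, highest 3). Two negative components —
meat products (g/d) and total fat (E%, percent of energy intake) — score
in reverse order. Alcohol scores 1 point below 20 g ethanol/d and 0 at or
above. Ties share a quartile, so quartile sizes are unequal for
narrow-ranged components.

**HPL depression scale (0–18).** One point per symptom-indicating answer
over 18 dichotomous items; a total ≥ 5 flags clinically significant
depressive symptoms.

**Quade's non-parametric ANCOVA.** Outcome and covariates are
rank-transformed (mid-ranks for ties), covariate effects are removed by
least squares on the ranks, and HNDS quartiles are compared by a one-way
ANOVA F test on the residuals with (k − 1, N − k) degrees of freedom —
appropriate for a right-skewed count outcome. Companion estimates:
covariate-adjusted per-quartile means with 95% CIs (parametric ANCOVA at
covariate means), the extreme-quartile difference (lowest minus highest
adherence), and a linear trend test across the quartile index. Two
adjustment sets mirror the cohort analysis: model 1 (age, examination
year, energy intake) and model 2 (model 1 + leisure-time physical
activity, socio-economic status, smoking, marital status).

**Quantile regression.** Conditional-quantile fits of the HPL total on
the HNDS with model-2 covariates at τ = 0.33 and 0.66, minimising the
check loss ρ_τ(r) = r(τ − 1[r < 0]) by smoothed IRLS plus an exact
vertex polish, with seeded pairs-bootstrap percentile CIs.

**Synthetic cohort generator.** A calibrated simulator of the emulated
cohort (by default 2603 men aged 42–60, examined 1984–1989): a latent
diet-quality factor drives correlated log-normal component intakes, a
depression liability (`effect_size` × diet factor + noise) drives HPL
items through a logistic item model, and covariates couple to the diet
factor via Gaussian copulas so the usual confounding gradients appear.
Defaults reproduce the printed cohort statistics (mean HNDS ≈ 12.8,
SD ≈ 4; mean HPL ≈ 1.9, SD ≈ 2.1; prevalence of totals ≥ 5 ≈ 11%).
Missingness injection and the exclusion step reproduce the
2682 − 79 → 2603 roster arithmetic in expectation.

## Worked example

```r
library(hnds)
cfg <- run_config(
  synthetic = synthetic_config(n_participants = 2682, seed = 1),
  bootstrap_B = 1000, seed = 1
)
report <- run_study(cfg)
print(report)
```

```
Study run: 2607 of 2682 retained (75 excluded)
model1: Quade F = 2.65 (p = 0.04734); extreme-quartile diff = 0.316 [0.076, 0.556], p = 0.009999; p trend = 0.006246
model2: Quade F = 1.88 (p = 0.1315); extreme-quartile diff = 0.302 [0.052, 0.553], p = 0.01798; p trend = 0.02348
quantile tau = 0.33: beta(HNDS) = -0.0000 [-0.0440, 0.0000], p = 1
quantile tau = 0.66: beta(HNDS) = -0.0000 [-0.0000, 0.0000], p = 1
```

Reading the output: 75 of 2682 simulated men lacked a complete diet or
HPL block and were excluded (the block-missingness rate is 79/2682, so
the count varies by seed). Under the default built-in effect
(`effect_size = -0.10`), men in the lowest-adherence quartile average
about 0.3 HPL points more than the highest-adherence quartile after full
adjustment, with the trend across quartiles significant — the direction
and magnitude such cohort analyses report. The quantile slopes are
exactly zero here: on an integer symptom count a conditional quantile is
a step function, and with a weak effect the flat fit is the true
check-loss optimum (an independent solver reaches the same objective);
see the methods vignette. With `output_dir` set, `run_study()` also
writes the descriptives table, per-model adjusted means and summaries,
the complete-case sensitivity rerun, the quantile-regression table and a
JSON metadata block, all deterministic given the seeds.

A command-line wrapper with `simulate` / `score` / `analyze` / `run`
subcommands lives at `inst/cli/hnds.R`.

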