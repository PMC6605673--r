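---
title: "Cross-validating body composition prediction equations against DXA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validating body composition prediction equations against DXA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxacv)
```

## The problem

Anthropometry (skinfold) and bioelectrical impedance (BIA) prediction
equations are the accessible way to estimate body fat (BF) and fat-free mass
(FFM) outside a densitometry lab, but every such equation was fitted on a
particular population, and applying it elsewhere can give systematically
wrong estimates. In lean athletic populations — the motivating case is
female classical ballet dancers — this matters clinically: body composition
is monitored against both performance and health (menstrual function, bone
health, disordered eating risk), and a biased equation can mask or invent
change. Before an equation is adopted for a population it should be
cross-validated against a reference method, today usually dual-energy X-ray
absorptiometry (DXA).

`dxacv` packages that cross-validation as a reusable, tested pipeline: a
registry of published equations with per-equation eligibility and unit
handling, the agreement-statistics chain, report/plot-data export, a
synthetic-cohort generator for testing, and the measurement-QC utilities
that precede such an analysis.

## The equation registry

The registry (`equation_registry()`) carries 19 evaluable closed forms —
8 anthropometry, 11 BIA — plus a placeholder for the RJL Systems
manufacturer equation, whose formula is proprietary and undisclosed; the
pipeline accepts user-supplied predictions for it via `external_pred`
instead of evaluating it.

Three conventions deserve explanation:

* **Output kinds.** Most skinfold equations predict body density (g/ml),
  converted to BF% by the Siri two-compartment relation
  $\mathrm{BF\%} = 495/\mathrm{BD} - 450$; one (Slaughter) predicts BF%
  directly; one (Hergenroeder) predicts FFM in kg, converted to BF% as
  $100\,(W - \mathrm{FFM})/W$. BIA equations predict FFM in kg, compared on
  the FFM% scale ($100\,\mathrm{FFM}/W$). Anthropometry equations are always
  compared on BF% and BIA equations on FFM%; the two families are never
  mixed on one scale.
* **Height units.** Secondary transcriptions of BIA equations often state a
  single height unit globally, but the printed coefficient magnitudes are
  only dimensionally consistent with the conventions of the original
  publications: centimeters for the resistance-index ($H^2/R$) and bare-$H$
  terms of Chumlea, Segal, Gray, Lukaski, Houtkooper, Kyle, Sun and both
  Yannakoulia equations, and meters in Deurenberg's two equations (whose
  printed $10^4$ factor on $H^2/R$ restores the cm$^2$ scale). Reading those
  cm-convention terms in meters yields fat-free masses below 1 kg, which is
  how the conflict is resolved: each registry entry carries its own
  `height_unit`, and cohort heights (always stored in meters) are converted
  at evaluation time.
* **Age eligibility.** Each equation is applied only to subjects inside the
  closed age range of its development sample, in completed years (a
  16-year-old is eligible for a 16–68 range). This is the only row filter
  besides per-equation missing-input exclusion.

Two transcription ambiguities in circulating versions of these formulas are
resolved in the registry and recorded in each entry's formula string: the
Durnin–Womersley prefactor is read as
$\mathrm{BD} = 1.1567 - 0.0717\log_{10}(\Sigma SF)$ (the standard published
form), and the Slaughter female equation as
$\mathrm{BF\%} = 1.33\,\Sigma - 0.013\,\Sigma^2 - 2.5$ with
$\Sigma = TR + SE$ (triceps plus subscapular; $-2.5$ is the female
constant). The Jackson–Pollock 1975 quadratic term is taken over the same
four-fold sum as its linear term. Sex terms code female = 0, male = 1.

## The agreement chain

For each equation, predictions on the eligible subset are paired with the
matching DXA column and pushed through a three-stage chain
(`validity_verdict()`), at a common significance level $\alpha = 0.05$:

1. **Correlation screen** — Pearson r between equation and DXA must be
   significant ($p < \alpha$). A method that does not even track the
   reference is rejected outright.
2. **Agreement** — a one-sample t-test of the differences
   $d_i = \mathrm{eq}_i - \mathrm{DXA}_i$ against zero must be
   *non-significant* ($p > \alpha$): the roles are inverted relative to a
   usual test, a small p-value here means systematic over- or
   under-estimation.
3. **Proportional bias** — run only when stages 1 and 2 pass. The
   Bland–Altman statistics are computed (mean difference, sample SD with the
   $n-1$ denominator, limits of agreement at $\pm 1.96\,\mathrm{SD}$ —
   the fixed conventional multiplier, not a t quantile), and the differences
   are regressed on the per-subject means $m_i = (\mathrm{eq}_i +
   \mathrm{DXA}_i)/2$ by ordinary least squares. A significant slope
   ($p < \alpha$) means the disagreement depends on the magnitude of the
   measurement — proportional bias — and invalidates the equation;
   equality ($p = \alpha$) is assigned to pass. The slope sign gives the
   bias direction; adjusted $R^2$ (which can be negative near a null
   slope), the standard error of estimate
   $\mathrm{SEE} = \sqrt{\mathrm{SSE}/(n-2)}$, and the slope p-value are
   reported.

The verdict is `valid` only when every stage reached passes; otherwise it
names the first failing stage. Stage 3 exists *iff* stages 1 and 2 passed —
an invariant the tests enforce over generated cohorts. Equations that fail
remain in the report (the verdict column, not omission, encodes failure);
equations with an empty eligible subset are reported `not_evaluable` with
n = 0. All tests are two-sided and no multiple-testing correction is applied
across equations — each equation is judged on its own, as is conventional in
this literature. Confidence intervals on the limits of agreement themselves
are out of scope.

An auxiliary box-plot screen (`outlier_flags()`) flags extreme values lying
more than 3 box lengths (interquartile ranges) beyond the quartiles;
quartiles use linear interpolation between order statistics
(`stats::quantile` type 7), a choice the run configuration exposes since
box-plot conventions differ across software.

```{r}
cfg <- scenario_config(n = 37, seed = 42, scenario = "agreement",
                       noise_sd = 2)
cohort <- inject_bias(generate_cohort(cfg), cfg)
run <- run_crossvalidation(cohort)
report_table(run)[, c("equation", "n", "equation_mean_sd", "r", "p", "verdict")]
```

## The synthetic cohort generator

No participant-level data accompany studies of this kind, so the generator
(`generate_cohort()`) is the package's test bed. It emulates a cohort of
young female dancers through a single latent adiposity factor
$a \sim N(0,1)$ per subject:

* **Skinfolds** are log-normal at the published marginals (mean/SD or
  median/quartiles, as each was reported), each log-skinfold loading on $a$
  with coefficient `adiposity_loading` (default 0.8), so pairwise skinfold
  correlations are approximately $0.8^2 = 0.64$ — the strong mutual
  correlation real skinfolds show.
* **DXA BF%** is affine in $a$ (loading 0.9) at marginal 28.37 (7.01)%,
  clipped to [5, 50]% — bounds chosen to keep every equation's inputs and
  outputs in-domain; FFM% = 100 − BF% (two-compartment; a `bone_slack_kg`
  knob shifts the kg bookkeeping to emulate three-compartment DXA
  reporting, default 0 so mass conservation is exact).
* **Weight** is normal at 51.44 (5.49) kg with a 0.4 loading on $a$;
  **height** normal at 1.60 (0.042) m. A printed height SD of 0.42 m is
  physically implausible for this population and is read as a misprint;
  0.042 m is the realistic value used.
* **Resistance** follows the BIA plumbing in reverse: proportional to
  $H_{cm}^2/\mathrm{FFM}_{kg}$, rescaled so the sample mean hits the 672 Ω
  marginal exactly, plus 25 Ω of measurement noise; **reactance** truncated
  normal around 68 Ω.
* **Ages** are completed years from a mixture calibrated to a cohort of 17
  adolescents (14–17) and 20 adults skewed young, median ≈ 19, truncated at
  49.

Everything is drawn under `withr::with_seed`, so a (config, seed) pair
regenerates the cohort bit-identically and the caller's RNG stream is
untouched.

What the generator does **not** emulate: real DXA error structure (scan
repositioning, hydration effects), secular and maturation trends in
adolescent body composition, non-log-normal skinfold tails, or any
dependence of BIA reactance on adiposity. Tests passing on synthetic
cohorts therefore demonstrate that the *pipeline* is correct and well
calibrated, not that any particular equation is valid for a real
population.

### Controlled bias injection

`inject_bias()` rewrites the DXA reference on the target equation's
comparison scale so the differences follow
$d = b_0 + \text{slope term} + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$. Because $d$ and $m$ are algebraically entangled
($m = p - d/2$ once the prediction $p$ is fixed), naively setting the slope
term to $b_1(m - \bar m)$ would give a fitted slope biased toward zero, and
noise alone induces a spurious negative slope (the classical artifact of
regressing differences on means when only one method is noisy). The
construction slope is therefore solved numerically (`uniroot`) so that the
OLS slope of $d$ on $m$ has expectation exactly $b_1$, given the sample
variance of the predictions and $\sigma^2$; with $\sigma = 0$ the identity
is exact. The slope term is centered on the mean prediction so that $b_0$
alone controls the mean difference and $b_1$ alone the proportional bias.
Injection noise uses a seed offset (+1001) from the cohort seed so the two
draws are independent but jointly reproducible.

Operating characteristics, each recomputed by `scripts/acceptance.R` and
pinned by the test suite (replicate counts chosen to hold Monte-Carlo error
near half a percentage point while keeping the default run in tens of
seconds): under the agreement scenario the stage-2 t-test rejects in
4–6% of 2,000 replicates at n = 30, as does the stage-3 slope test under
independent differences and means; a constant bias of 5 BF-percentage
points with σ = 2 at n = 30 yields an invalid verdict in ≥ 99% of 500
replicates; a proportional bias of slope 0.5 with σ = 1 at n = 100 is
flagged by the stage-3 regression in ≥ 95% of 500 replicates with mean
fitted slope within 0.05 of 0.5. The proportional-bias rate is measured by
applying the stage-3 regression to each replicate's difference series: it
is the detection power of that test, cleanly separated from stage 2's own
5% false-rejection noise (by construction the proportional scenario leaves
the mean difference at zero).

## Measurement QC

Three small utilities mirror the quality-control steps that precede such a
study:

* `triplicate_mean_with_tolerance()` — skinfolds are taken in triplicate;
  the mean is used only if no measurement deviates from the anchor by more
  than 10%. The anchor is the triplicate median by default (the most robust
  reading of "10% of the value of each measure"); anchoring on the mean is
  a documented option.
* `tem()` — technical error of measurement in Dahlberg's duplicate form
  $\sqrt{\Sigma d^2 / 2n}$, absolute and as % of the grand mean;
  intra- vs inter-rater TEM differ only in which pairs are supplied.
* `repeatability_cv()` and `least_significant_change()` — per-subject CV of
  repeated scans, and the ISCD precision convention: RMS of per-subject SDs
  and LSC = 2.77 × RMS-SD (95% two-sided; the multiplier is an argument
  for other confidence levels).

## Numerical choices and degenerate inputs

* No rounding anywhere in computation; `report_table()` formats to 2
  decimals for means/SDs and 3 for r, printing p-values below 0.0005 as a
  bound, with raw precision retained in `run$results` and `report.csv`.
* Sample SDs use the $n-1$ denominator throughout.
* The Siri fixed point 495/1.1 − 450 is zero only to machine precision
  (≈ 6e−14) because 1.1 is not representable in binary floating point;
  identities are asserted at 1e−12.
* Constant (zero-variance) series: the correlation screen raises a typed
  degeneracy error, which the verdict absorbs as `invalid_stage1` with a
  note; the t-test returns t = 0, p = 1 on exactly-zero differences and a
  flagged p = 0 on constant nonzero ones; the bias regression returns slope
  0, p = 1 (flagged) on constant differences and errors on constant means.
  Exact affine difference–mean relations legitimately yield SEE = 0 and
  adjusted R² = 1. Nothing returns silent `NaN`.
* Skinfold sums ≤ 0 inside a log10 raise a domain error — they indicate
  corrupt input, not a computable prediction. Fat-free-mass predictions
  outside physiology (FFM < 0 or > weight) are returned with an
  implausibility flag rather than dropped, so they remain reportable.

## Scope and limitations

The per-equation sample sizes of any particular published study cannot be
reconstructed without its participant ages; the pipeline reproduces the
eligibility *rule*, not specific printed n values. The package does not
refit equation coefficients, model the reference methods the equations were
originally validated against (hydrostatic weighing, TOBEC, isotope
dilution), compute anthropometric z-scores (which require external growth
reference tables), or render figures — it emits plot-ready data
(`difference_plot_data()`, `bland_altman_plot_data()`) for any plotting
front end. Command-line wrappers for validation, simulation and QC live in
`system.file("scripts", package = "dxacv")`.
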