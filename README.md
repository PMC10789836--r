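# mealtrial

Metabolic modelling and trial statistics for randomized dietary
interventions in type 2 diabetes, built around the mixed meal tolerance
test (MMTT).

Clinical trials of meal-timing diets (for example early time-restricted
carbohydrate intake, "eTRC", versus a Mediterranean-style control)
measure glucose, insulin and C-peptide during a standardized meal,
monitor interstitial glucose for weeks with a flash sensor, and track
outcomes over a multi-week intervention. `mealtrial` implements the full
quantitative chain for such trials:

- **Insulin secretion by C-peptide deconvolution.** C-peptide is
  co-secreted with insulin but not cleared by the liver, so the insulin
  secretion rate ISR(t) can be reconstructed from plasma C-peptide by
  inverting the population two-compartment kinetic model (rates k01,
  k12, k21 and volume V from age, body surface area and clinical class).
  `deconvolve_isr()` solves the non-negative penalized least-squares
  problem

      min ‖C_obs − F(ISR)‖² + λ‖D²ISR‖²,  ISR ≥ 0

  where `F` is the exact forward model (`forward_cpeptide()`) and `D²`
  a curvature penalty, with λ set by the discrepancy principle.

- **Beta cell function modelling.** `fit_beta_cell()` fits the
  two-component secretion model

      ISR(t) = P(t)·max(0, ISR@5.5 + β-GS·(G(t) − 5.5)) + β-RS·max(0, dG/dt)

  yielding beta cell glucose sensitivity (β-GS, the dose-response
  slope), ISR at the 5.5 mmol/l reference glucose, rate sensitivity
  (β-RS) and a smooth positive potentiation factor P(t) with time-mean 1,
  summarized by the ratio of its 160–180 min to 0–20 min means
  (`potentiation_ratio()`).

- **Metabolic indices.** HOMA-IR, the Matsuda index, fasting and total
  insulin clearance (ISR/insulin ratios), the fatty liver index,
  HbA1c IFCC↔NGSP conversion, meal energy fractions and Harris–Benedict
  energy prescriptions.

- **Flash glucose monitoring metrics.** `cgm_summary()` computes
  wear-time-weighted mean, CV, and the time-in-ranges family (below
  3.9, within [3.9, 10], above 10, above 7.8 and above 6.7 mmol/l);
  `cgm_daily_profile()` gives ambulatory median/10th/90th percentile
  profiles, and `count_postprandial_peaks()` counts meal excursions in
  the smoothed average day.

- **Trial statistics.** Monte-Carlo power for the two-sided
  Mann–Whitney test (`power_mannwhitney()`), two-way repeated-measures
  ANOVA with diet, group and diet × group terms (`rm_anova()`, plus
  within-test time via `mmtt_anova()`), exact nonparametric two-group
  tests (`compare_groups()`), Spearman correlation with exact
  small-sample p-values (`spearman_test()`), tertile stratification by
  after-lunch carbohydrate share (`tertile_stratify()`) and
  dual-assessor food-diary reconciliation with the 20% dispute rule
  (`reconcile_diaries()`).

- **Synthetic cohort generator.** Because participant-level trial data
  are typically not deposited, `simulate_cohort()` generates everything
  the pipeline consumes — MMTT profiles forward-simulated from known
  beta cell parameters, 14-day CGM traces with arm-specific meal
  excursions, food diaries with configurable carbohydrate timing and a
  two-arm longitudinal outcome table with prescribed effects — so every
  stage is testable against ground truth.

## Worked example

```r
library(mealtrial)

# one synthetic subject with known physiology
cfg  <- simulation_config(seed = 42)
coh  <- simulate_subjects(cfg)
subj <- coh$truth[[1]]
prof <- simulate_mmtt(subj, cfg, seed = 42)

# reconstruct the secretion rate from the sampled C-peptide
kin <- subj$kinetics
isr <- deconvolve_isr(prof$data$time, prof$data$cpeptide, kin)

# fit the beta cell model to glucose + reconstructed ISR
fit <- fit_beta_cell(prof$data$time, prof$data$glucose, isr, seed = 1)
fit
#> Beta cell function parameters
#>   glucose sensitivity: 96.5 pmol/min per mmol/l
#>   ISR at 5.5 mmol/l:   389.0 pmol/min
#>   rate sensitivity:    0.0 pmol per mmol/l
#>   potentiation ratio:  1.359

subj$betacell$glucose_sensitivity   # ground truth for this subject
#> [1] 153.8913

homa_ir(prof$data$glucose[1], prof$data$insulin[1])
#> [1] 21.70396
```

The fitted glucose sensitivity is attenuated relative to the generating
value: reconstructing ISR from nine C-peptide samples smooths the
secretion peak, which flattens the apparent dose-response slope and
inflates the intercept. The recovery tests quantify this (fits on exact
model output recover β-GS and ISR@5.5 to within 2%; the two-stage
pipeline estimate is attenuated but rank-preserving). The HOMA-IR value
is this subject's fasting index from the noisy sampled panel — this
particular synthetic subject sits at the hypersecreting,
insulin-resistant end of the generated cohort.

A complete end-to-end run — simulate, deconvolve, fit, indices, CGM
summaries, trial ANOVA, tertile analysis, manifest and report — is one
call:

```r
run_pipeline(simulation_config(), out_dir = "pipeline-out")
```

or from the shell,

```sh
Rscript scripts/run_pipeline.R --out pipeline-out --seed 42
```

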