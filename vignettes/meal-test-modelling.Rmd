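---
title: "Meal-test metabolic modelling and trial statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal-test metabolic modelling and trial statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealtrial)
```

This vignette is the package's account of its models, numerical choices
and limitations. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

Randomized dietary trials in type 2 diabetes commonly rest on three
measurement layers: a mixed meal tolerance test (MMTT) with blood
sampling at 0, 15, 30, 45, 60, 90, 120, 150 and 180 min (glucose,
insulin, C-peptide); flash monitoring of interstitial glucose over
about 14 days; and a longitudinal outcome table over a 12-week
intervention with visits every 4 weeks. The scientific quantities of
interest — insulin secretion, beta cell function, insulin clearance and
sensitivity, glycaemic time-in-range, treatment effects — are all
*derived*, and each derivation involves modelling choices. This package
makes those choices explicit, testable and reproducible.

## C-peptide kinetics and deconvolution

C-peptide is secreted equimolarly with insulin but escapes hepatic
extraction, so plasma C-peptide is the standard window onto the insulin
secretion rate (ISR). The package uses the population two-compartment
model: a central (plasma) compartment with irreversible loss `k01` and
exchange (`k21` out, `k12` back) with a peripheral compartment, central
volume `V`. `population_kinetics()` derives subject-specific constants
from the classical population regression — a bi-exponential impulse
response with amplitude fraction and short half-life fixed per clinical
class (normal, obese, type 2 diabetes), a long half-life linear in age,
and a volume linear in Du Bois body surface area — shipped as the
documented, overridable table `kinetics_coefficients()`. The conversion
from bi-exponential `(A, a, B, b)` to rates is exact:
`k12 = A·b + B·a`, `k01 = a·b/k12`, `k21 = a + b − k12 − k01`.

`forward_cpeptide()` solves the linear system exactly per grid step via
the eigendecomposition of the 2×2 system matrix, with secretion held
piecewise constant over each step (left-continuous). The tests verify
it against an adaptive stiff ODE solver to better than 0.1% and check
mass balance (total secreted = eliminated + stored) to numerical
precision. At constant secretion `S`, the steady state is
`S/(k01·V)` — a closed form used both as a unit test and as the initial
condition below.

`deconvolve_isr()` inverts the forward model by non-negative penalized
least squares on a 1-min reconstruction grid:

\[
\min_{u \ge 0}\; \lVert C_{obs} - F(u)\rVert^2
  + \lambda \lVert D^2 u \rVert^2 .
\]

Numerical choices:

* **Initial condition.** Fasting steady state from the mean of the
  baseline sample(s); the peripheral compartment starts in exchange
  equilibrium. The implied basal secretion `k01·V·C(0)` is reported.
* **Grid.** 1 min — much finer than the 15–30 min sampling; the
  forward operator is a lower-triangular Toeplitz convolution built
  from the exact step response, so the cost is negligible.
* **Regularization.** Second differences of ISR (curvature). λ defaults
  to the discrepancy principle: among a wide log-spaced grid, the value
  whose residual SD best matches an assumed relative assay error
  (`target_cv`, default 5%) is selected. The search uses the
  unconstrained ridge solution (a direct linear solve); the selected λ
  then receives the full non-negative solve. When the ridge solution is
  already non-negative it satisfies the KKT conditions of the
  constrained problem and is used as is; otherwise an active-set NNLS
  solver finishes the job.
* **Non-negativity.** Guaranteed by the constrained solver, matching
  the physiology (no negative secretion).

Properties enforced by tests: noise-free round trips
(`deconvolve(forward(·))`) recover a smooth ISR to below 2% RMSE of the
peak; total AUC survives 3% multiplicative assay noise to within 5% on
average over seeded replicates at the clinical 9-point sampling grid;
doubling `V` doubles the recovered ISR; a constant C-peptide
concentration inverts to `k01·V·C` within 1%.

## The beta cell model

Insulin secretion during a meal is modelled as the sum of two
components:

\[
ISR(t) = P(t)\,\max\{0,\; ISR_{5.5} + \beta_{GS}\,(G(t) - 5.5)\}
       + \beta_{RS}\,\max\{0,\, dG/dt\},
\]

a quasi-linear glucose dose-response (slope β-GS, the *glucose
sensitivity*; intercept ISR@5.5 at the 5.5 mmol/l reference) modulated
by a positive, slowly varying *potentiation* factor `P(t)`, plus a
*rate sensitivity* component active while glucose rises (the
anticipatory component of early secretion; applying it to positive
dG/dt only follows the convention of this model family). `P` is
summarized by the ratio of its 160–180 min mean to its 0–20 min mean,
which is > 1 when secretion is progressively potentiated during the
test.

Identifiability requires a normalization: `P` is constrained to
time-mean 1 over the test window, so its shape is separated from the
dose-response scale. `fit_beta_cell()` parametrizes
`P = exp(spline)` — a natural cubic spline with knots every 30 min,
basis columns centred so log-potentiation has mean zero during
optimization, with exact renormalization of the time mean afterwards
(the model is invariant under exchanging a scale factor between `P` and
the dose-response, so this is a pure reparametrization).

* **Variable projection.** Given the spline coefficients the model is
  linear in (ISR@5.5, β-GS, β-RS); these are profiled out per objective
  evaluation (ordinary least squares, falling back to non-negative
  least squares when the unconstrained solution leaves the feasible
  cone). The outer optimizer then works on 6 spline coefficients only —
  this removes most of the non-convexity of the joint problem.
* **Smoothness penalty.** Mean squared second difference of `P`,
  weighted by `penalty × mean(ISR²) × span⁴` so the weight is
  dimensionless; the default `penalty = 1e-4` leaves noise-free
  recovery essentially unbiased (β-GS and ISR@5.5 within 2% in the
  tests) while stabilizing the potentiation shape against 5% ISR noise
  (median β-GS error under 15% over seeded replicates).
* **Multistart.** 5 seeded L-BFGS-B starts (flat potentiation plus
  jittered shapes); the lowest penalized objective wins; ties cannot
  occur in practice but would resolve to the first minimum found.
  Non-convergence is flagged in the returned object, never silent, and
  a negative fitted dose-response over the observed glucose range
  raises a diagnostic warning.
* **dG/dt.** From the derivative of a smoothing spline through the
  sampled glucose (15–30 min gaps make raw finite differences
  unusable); when glucose is supplied on the ISR grid itself, an
  interpolating natural spline derivative is used instead.

A known limitation, stated rather than hidden: when ISR is first
reconstructed by deconvolution from sparse C-peptide samples, the
smoothing intrinsic to the inverse problem attenuates the secretion
peak, which biases the fitted β-GS downward (roughly 25–30% at the
9-point clinical grid in the pipeline smoke tests) while preserving
ranking across subjects. Parameter-recovery claims at the 2% level hold
for fits on exact model output, which is what the module-level tests
and the acceptance battery assert; between-group comparisons of the
two-stage estimates remain valid because the attenuation applies to
both arms alike.

## Metabolic indices

All closed-form definitions, with units handled internally:

* `homa_ir(G, I) = G × (I/6.0) / 22.5` with glucose in mmol/l and
  insulin in pmol/l (6.0 pmol/l per µU/ml, configurable).
* `matsuda()` uses `10000/√(G₀·I₀·Ḡ·Ī)` in mg/dl and µU/ml, with
  trapezoidal time-weighted means over the full 0–180 min test by
  default — the test is 180 min and the grid non-uniform, so the
  classic five-point 0–120 variant is available behind
  `variant = "classic120"` rather than being the default. Note the
  index scales as 1/s under a uniform insulin scaling s (insulin enters
  both as fasting value and as mean).
* `insulin_clearance()`: fasting mode `ISR(0)/I(0)`; total mode
  `AUC(ISR)/AUC(insulin)` over the overlapping support, trapezoidal.
* `fatty_liver_index()`: logistic score
  `y = 0.953 ln(TG) + 0.139 BMI + 0.718 ln(GGT) + 0.053 waist − 15.745`,
  `FLI = 100·eʸ/(1+eʸ)`, triglycerides in mg/dl per the index's original
  definition (mmol/l input converted at 88.57).
* `hba1c_ifcc_to_ngsp()`: the affine master equation
  `% = 0.09148 × mmol/mol + 2.152`, displayed with half-up rounding to
  one decimal (49 → 6.6, 44 → 6.2, 64 → 8.0).
* `energy_fractions()`: Atwater factors (4/9/4 kcal/g at 4.184 kJ/kcal)
  against the *stated* label energy, not forced to sum to 100 — food
  labels are frequently inconsistent, and for the standard 1255 kJ test
  meal the carbohydrate and protein fractions reproduce the label
  (49.3% and 16.0%) while fat computes to 36.0%.
* `energy_requirement()`: Harris–Benedict resting expenditure plus
  activity, minus a constant daily deficit sized so the cumulative
  deficit over the prescription period equals
  `target_loss_fraction × weight × 32220 kJ/kg` (7,700 kcal/kg body
  tissue, the conventional energy-density constant used by
  energy-deficit calculators). Prescriptions below 80% of resting
  expenditure are flagged.

## Flash glucose monitoring

`cgm_summary()` weights each sample by the time to its successor,
capped at twice the nominal interval — samples followed by a longer gap
contribute no wear time, so gaps shrink the denominator instead of
biasing the percentages. Boundary conventions: time in range is the
closed interval [3.9, 10] mmol/l (consensus-guideline style; "within"
is ambiguous in prose), "below" and "above" are strict, which makes
TBR + TIR + TAR an exact partition (asserted on every random trace in
the tests, along with the monotone chain
`%>6.7 ≥ %>7.8 ≥ TAR>10`). CV uses the population (n-denominator) SD.
At least 24 h of valid wear is required, and a configurable
leading-hours exclusion (default 0) covers sensor warm-up if wanted.
`cgm_daily_profile()` pools days by clock time and reports per-bin
median and 10th/90th percentiles; `count_postprandial_peaks()` smooths
the 24-h mean profile with a circular 2-h moving average and counts
local maxima with at least 0.5 mmol/l prominence over ±3 h.

## Trial statistics

* `power_mannwhitney()` estimates power by simulation. With continuous
  normal draws there are no ties, so the exact two-sided p-value is a
  function of U alone; the lookup is precomputed from the exact
  Wilcoxon distribution once per call, making 10,000 replicates a
  matter of seconds. A unit test pins the lookup to `wilcox.test`
  per replicate, and an analytic cross-check compares the simulated
  power to two-sample t-test power at 95.5% asymptotic relative
  efficiency.
* `rm_anova()` is the classical within/between partition
  (`aov` with an `Error(subject/visit)` stratum): between-subject
  factor group, within-subject factor visit (the diet/time effect),
  and their interaction, on complete cases (subjects missing a visit
  are dropped and counted). No sphericity correction is applied by
  default; Greenhouse–Geisser is available behind `gg_correction`
  (Box's epsilon from the doubly-centred within-subject covariance).
  With only two visits sphericity is trivially satisfied. Type-I
  calibration at the nominal 5% level is asserted on simulated nulls.
* `mmtt_anova()` adds the within-test time factor
  (`Error(subject/(visit*time))`) and reports all seven terms,
  including time × diet and time × group interactions.
* `compare_groups()` uses exact enumeration for Mann–Whitney when both
  groups have ≤ 10 observations and no ties (beyond that, the
  tie-corrected continuity-corrected normal approximation) and exact
  hypergeometric enumeration for Fisher's 2×2 test. `spearman_test()`
  enumerates all permutations for n ≤ 8 and uses the t-approximation
  otherwise. All three are pinned to independent brute-force oracles in
  the tests.
* `tertile_stratify()` computes each subject's after-lunch carbohydrate
  share — the median across diary days of
  `(dinner + post-lunch other carbohydrate)/(total carbohydrate)` —
  cuts at the empirical 33.3/66.7 percentiles, and compares outcome
  changes between the extreme tertiles by Mann–Whitney. "After lunch"
  is defined by meal slot, not clock time, with the generic `other`
  slot counted as post-lunch. Fewer than 6 subjects or an
  all-identical metric is rejected as degenerate.
* `reconcile_diaries()` applies the dual-assessor rule: if the two
  estimates of energy *or* total carbohydrate differ by ≥ 20% of their
  mean, the diary is flagged and a third assessment (when present)
  resolves it by the median of the three; otherwise the consensus is
  the mean. No multiplicity adjustment is applied anywhere (α = 0.05
  two-sided throughout).

## The synthetic cohort: what it emulates and what it does not

The generator (`simulation_config()`, `simulate_subjects()`,
`simulate_mmtt()`, `simulate_cgm()`, `simulate_trial()`,
`simulate_cohort()`) is a first-class, tested module: it is the only
data source the pipeline needs, and every stage can be checked against
the ground truth it records.

Defaults, chosen once to bracket a realistic type-2-diabetes trial
cohort (overweight, age around 67, HbA1c near 49 mmol/mol) and then
left alone:

| quantity | default | rationale |
|---|---|---|
| arms | 14 + 13 randomised, 2 dropouts each | two-arm trial with ~15% attrition |
| visits | weeks 0/4/8/12; MMTT at 0 and 12 | standard 12-week design |
| MMTT sampling | 0,15,30,45,60,90,120,150,180 min | clinical grid |
| fasting glucose | U(6.6, 8.9) mmol/l | well-controlled T2D span |
| β-GS | lognormal, median 100 pmol·min⁻¹ per mmol/l | T2D range |
| ISR@5.5 | lognormal, median 80 pmol/min | consistent fasting secretion |
| β-RS | U(300, 800) pmol per mmol/l | T2D range |
| potentiation ratio | U(1.3, 1.9), linear mean-1 ramp | moderate late potentiation |
| insulin clearance | U(1.2, 2.0) l/min, first-order lag 0.15/min | plausible fasting insulin; the simplest identifiable insulin model |
| HbA1c effects | diet −4, interaction +1 (mmol/mol), residual SD 3 | arm-level changes of −3 vs −4 and the power assumption |
| CGM | 14 d at 15 min; bumps 2.5/2.2/3.0 mmol/l, SD 40 min; AR(1) ρ = 0.8, SD 0.4; circadian 0.3 | flash-sensor convention (interval and sensor-noise autocorrelation are assumptions, both configurable) |
| meals | 08:00 / 13:00 / 20:00 | no clock times are standard; configurable |
| after-lunch carb share | 8% (eTRC) vs 30.5% (Med) | carbohydrate-timing contrast of the two regimens |

Dinner excursions are present only in the Med arm, which is what makes
the smoothed average day show two postprandial peaks under eTRC and
three under Med — a property the tests count rather than assume.

What the generator does **not** emulate: physiological meal absorption
(the glucose excursion is a parametric rise-and-fall curve, not an
absorption model); incretin physiology (hormone series, if needed, are
generic noisy analytes); sensor drift, compression artefacts or missing
CGM data; non-linear insulin kinetics; dropout that is informative
rather than random. Consequently, green tests demonstrate that the
*computational chain* is correct and calibrated under known ground
truth — they do not validate the biology of any particular trial, and
effect-size conclusions transfer to real data only insofar as the
noise model (additive Gaussian assay error, AR(1) sensor noise,
subject random intercepts) is adequate.

Problem sizes used by the test suite and acceptance script — chosen as
comfortable desk-scale defaults — are: 10,000 power replicates, 100
noisy beta-cell recovery fits, 1,000 simulated ANOVA nulls, 50 noisy
deconvolution round trips, and a full pipeline on the default 27-subject
cohort.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → deconvolve → beta-cell fit →
indices → CGM summaries → trial statistics, writing CSVs in documented
dialects plus `manifest.json` (FNV-1a hash of the resolved
configuration, seed, package version, file inventory, CONSORT-style
randomised/completed/analysed accounting per arm) and a human-readable
report. Manifests contain no timestamps, so identical seeds yield
byte-identical manifests; `--resume` skips stages whose outputs exist.
All randomness is derived from the single config seed via fixed integer
offsets, and every simulation function restores the caller's RNG state.
Configuration can be loaded from YAML (`load_config()`), with unknown
keys reported all at once. Within the pipeline the deconvolution's
discrepancy target is set from the configured assay SD rather than the
generic 5% default, since the analyst of simulated data knows the assay
error exactly.
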