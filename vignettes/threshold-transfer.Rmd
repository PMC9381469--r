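---
title: "Level-wise calibration and diagnostic threshold transfer for spine QCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-wise calibration and diagnostic threshold transfer for spine QCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpineCalib)
```

## The problem

Opportunistic quantitative CT (QCT) extracts trabecular volumetric bone
mineral density (vBMD, mg hydroxyapatite per ml) from CT scans acquired for
unrelated indications. Accepted diagnostic cut-offs exist only for the lumbar
spine (ACR convention: osteoporosis at trabecular vBMD < 80 mg/ml, osteopenia
at < 120 mg/ml, applied to the mean over L1–L3). Many clinical scans — stroke
work-ups, cervical trauma — cover only the cervical or thoracic spine, where
absolute vBMD is substantially higher and those cut-offs do not apply.

SpineCalib implements the transfer of the lumbar cut-offs to every
cervicothoracic level (C2–T12) in three stages:

1. **Quality control.** Vertebrae with a Genant semiquantitative fracture
   grade ≥ 1 or a degeneration grade ≥ 2 are flagged and excluded from all
   density analysis — both processes spuriously *increase* measured vBMD.
   Exclusion is flag-based and idempotent; records are never deleted, so the
   pre-exclusion analysis can run on the same object.
2. **Level-wise calibration.** For each level ℓ, ordinary least squares of
   the level's vBMD on the per-patient lumbar reference (mean over surviving
   L1–L3): E[vBMD_ℓ] = a_ℓ · lumbar + b_ℓ, with the per-level Pearson r
   reported before and after exclusion.
3. **Threshold transfer.** The level-specific cut-off is the calibration
   line *evaluated at* the lumbar cut-off: threshold_x(ℓ) = a_ℓ · cutoff_x
   + b_ℓ.

### Why evaluation, not inversion

With a fitted line `level = a·lumbar + b` there are two candidate transfers:
evaluate the line at the lumbar cut-off, or invert it
(`(cutoff − b)/a`). They differ whenever r² < 1. SpineCalib evaluates:
the level-specific threshold should be the *expected level value* of a
patient sitting exactly at the lumbar cut-off, which is what a clinician
comparing a measured cervical value against the threshold needs. The bundled
reference table is consistent with evaluation only (every printed threshold
equals `slope · cutoff + intercept` to its one-decimal rounding), which also
resolves the regression direction: the per-level coefficients predict the
level *from* the lumbar reference.

Full precision is kept internally; `displayThresholds()` rounds half-up to
one decimal, and test comparisons against the bundled table use a
±0.1 mg/ml band to absorb that table's own rounding.

## The synthetic cohort generator

No per-patient data are distributed with the reference study, so the
generator provides a ground-truth-known population with the same statistical
structure. Design:

* **A single latent lumbar density per patient** drives all levels;
  conditional on it, levels are independent. This is the minimal structure
  able to reproduce a full per-level correlation profile and per-level
  linear couplings simultaneously.
* **Age and sex enter only through the latent mean** (level couplings are
  age-invariant): sex-specific value at age 18 and linear decline per year,
  plus between-patient scatter (SD 35 mg/ml). Ages are truncated-normal
  59.7 ± 18.3 years on [18, 96]; 105/260 of patients are women.
* **Couplings and noise.** Per-level slopes/intercepts default to the
  bundled reference coefficients. Per-level residual SDs are *derived* from
  the bundled r² profile via σ_ℓ = a_ℓ·σ_L·√(1/r² − 1), where σ_L is the
  closed-form marginal latent SD — so the model-implied Pearson profile
  (r ≈ 0.76 at C2 rising to ≈ 0.96 at T12) holds by construction
  (`expectedLevelCorrelation()`).
* **Fractures** attach to patients with logistic probability in the latent
  lumbar density (intercept 2.36, slope −0.03 per mg/ml, calibrated to
  ≈ 60/260 fractured patients and a fractured-patient lumbar mean near
  80 mg/ml); each fractured patient carries 1 + Poisson(1.6) fractured
  vertebrae placed thoracic/lumbar/cervical at 0.65/0.34/0.01 and graded
  uniformly over Genant 1–3 (no published grade breakdown — an assumption).
  Fractured vertebrae get a compression bias of N(30, 20) mg/ml truncated
  at 0.
* **Degeneration**: per-vertebra probability of grade ≥ 2 logistic in age
  (≈ 11% of vertebrae overall), 70/30 over grades 2/3, mild grade 1
  independently at 15%; grade ≥ 2 vertebrae get a sclerosis bias of
  N(40, 15) mg/ml truncated at 0. The direction (increase) is established;
  the magnitude is a field-plausible choice.
* **Contrast enhancement**: 46/260 scans, split evenly between arterial and
  venous phases with additive biases N(10, 4) and N(17, 5) mg/ml —
  plausible circulation-phase magnitudes, not published values.
* **Scanners**: the eight-scanner pool with the study's sampling weights;
  the HU↔vBMD coefficients are synthetic placeholders (real phantom
  equations are site-specific and unpublished), used only to emit an
  optional raw-HU assay.
* Measured vBMD is truncated below at 0 mg/ml; the latent lumbar value is
  clamped at 0 *before* driving the levels, which keeps the noiseless limit
  exactly linear.

The latent-line parameters (women: 171.7 mg/ml at age 18, −1.57/year; men:
172.0, −1.00/year) were calibrated once against the printed anchors — the
C4 age/sex group means, the sex-matched lumbar means (131.3 vs 155.5), the
fractured vs non-fractured means (80.0 vs 111.7) — and are asserted in tests
only to within ±25% of those anchors and in the printed directions, because
the anchors derive from one specific clinical cohort the generator does not
claim to reproduce numerically.

**What the generator does not emulate:** real scanner-to-scanner density
offsets, non-linear age trajectories (e.g. accelerated post-menopausal
loss), spatial correlation of degeneration along the spine, partial
thoracolumbar coverage patterns, and any image-level effects. Tests passing
on simulated cohorts therefore validate the *statistical machinery*, not
clinical transferability of any fitted numbers.

## Choices a user can change

| Parameter | Default | Unit | Why |
|---|---|---|---|
| lumbar cut-offs | 80 / 120 | mg/ml | ACR lumbar convention |
| `useDegenerationRule` (reference) | `TRUE` | — | see below |
| `r2Floor` (threshold reliability) | 0.3 | — | guards nonsense transfer on degenerate cohorts |
| t test variant | Welch | — | unequal variances are the safe default |
| age-match caliper | 5 | years | conventional epidemiological choice |
| classification boundary | strict `<` enters worse category | — | matches the "< 80 mg/ml" cut-off phrasing |
| patient aggregation | `worst` | — | screening intent: flag, don't diagnose |

**The lumbar-reference ambiguity.** The reference is defined over
"non-fractured" L1–L3, while degeneration-excluded vertebrae are excluded
from density assessment globally. Whether a degenerated (grade ≥ 2) lumbar
vertebra should enter the reference is therefore ambiguous; SpineCalib
excludes it by default and exposes `useDegenerationRule = FALSE` for the
literal non-fractured-only reading, rather than burying the choice.

**Policies.** The `rounded_regional` policy (cervical < 200, thoracic < 100,
lumbar < 80 mg/ml) is shipped as a *distinct* named policy from the exact
`table2` thresholds; the two disagree at several levels (e.g. C7
osteoporosis 153.2 vs the 200 rounding) and are deliberately not
reconciled. The rounded rule has no published osteopenia analogue, so by
default it distinguishes only osteoporosis from not-osteoporosis.

## Numerical and degenerate-input conventions

* OLS fits require ≥ 3 usable patients and nonzero variance in the
  regressor; both violations are rejections, not NA results.
* Per-level r with n < 3 is reported absent with a warning.
* The Fisher-z paired comparison of correlation profiles resolves
  zero-variance difference vectors explicitly (identical profiles → p = 1;
  constant nonzero shift → p = 0) instead of erroring; a sign-flip
  permutation test serves as the independent oracle in the test suite.
* Ties at a classification boundary take the better category; equality of
  cut-offs is rejected at construction.
* Missing grades are hard errors naming patient and level — a missing grade
  is never assumed to be 0.
* All randomness flows from one integer seed; the generator restores the
  caller's RNG state.

## Problem sizes used by the test suite

Unit tests run on hand-built cohorts of 1–6 patients against brute-force
oracles. Distributional checks use simulated cohorts of 260–2,000 patients;
parameter recovery uses 100 seeds at n = 2,000 (slopes within ±0.05,
intercepts within ±10 mg/ml for ≥ 95% of per-seed, per-level estimates —
at the C2 noise level, ±0.05 is only ~1.8 standard errors, so a joint
all-levels-per-seed criterion would be unattainable by construction);
correlation-profile direction checks use n = 800 over 3 seeds; the
Monte-Carlo confirmation of the correlation profile shape uses n = 20,000
once. These sizes put every sampling check several standard errors away
from its bound while keeping the default suite fast.

## Known limitations

* Calibration is linear and age-invariant; Deming/total-least-squares
  alternatives (relevant because the lumbar reference itself is noisy) are
  deliberately out of scope.
* Fracture-prediction performance of the transferred thresholds is not
  evaluated — that requires outcome data the package does not model.
* The bundled reference coefficients come from one retrospective
  single-center cohort; `fitAllCalibrations()` on local data is the
  intended path to site-specific thresholds.
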