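---
title: "Discriminative core sets of gait variables: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative core sets of gait variables: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The statistical procedure

The pipeline asks: which small combination of kinematic gait variables best
separates persons post-stroke from non-disabled controls in a cohort of
modest size (the default emulates 31 stroke / 41 control subjects)?

**Step I — screening.** Each candidate variable is modelled by ordinary
least squares on an intercept, a group indicator (1 = stroke) and the
covariates age (years), sex (0/1) and BMI (kg/m²). The group coefficient
therefore reads "stroke minus control, covariate-adjusted", and a variable
survives when its two-sided t-test gives p < α. Defaults: α = 0.05,
two-sided, deliberately unadjusted for multiplicity — screening here is a
triage step, not a confirmatory family of tests, and the downstream search
re-evaluates every survivor jointly. Models are fitted one variable at a
time: with ~60 outcomes and 72 subjects a joint multivariate model would be
ill-posed, and per-variable fits are the only reading under which the
design matrix stays full rank.

**Step II — exhaustive core-set search.** All subsets of 1 to
`max_size = 4` screened variables are enumerated (deterministically: by
size, then lexicographically) and each is scored by leave-one-out
cross-validation: a logistic regression without interactions is fitted to
the other *n* − 1 subjects and the held-out subject is classified
post-stroke iff its predicted probability strictly exceeds
`threshold = 0.5`. A probability exactly at the threshold classifies as
control ("strictly above" wins). The score is the misclassification rate
MR = wrong/*n*; confusion entries are reported as proportions of all *n*,
so TP + TN + FP + FN = 1 and MR = FP + FN. Rankings report *all* ties at a
given MR — at *n* = 72 the MR is quantized to 1/72 and ties are the rule,
not the exception — and top-k truncation keeps every set tied with the k-th
MR.

**Correlation context.** Spearman matrices over the variables of interest
are computed pooled and per group. Both are reported because they answer
different questions: a pooled rank correlation can exceed both within-group
correlations whenever the group means differ on both variables (the suite
constructs such a case), so pooled structure conflates group separation
with genuine within-group coupling.

## Logistic fitting and separation

The search fits hundreds of thousands of small logistic models, so the IRLS
loop lives in C++ (RcppArmadillo). Numerical contract:

* initialization at β = 0; convergence when the largest coefficient change
  falls below 1e-8 or the log-likelihood change below 1e-10; at most 50
  iterations;
* working weights floored at 1e-10 and the working linear predictor clamped
  at ±30 inside the update for stability;
* a fit is flagged as (quasi-)separated when the coefficient norm exceeds
  1e4 *or* the final linear predictor saturates (|η| > 25, i.e. fitted
  probabilities numerically at 0/1). Flagged fits are not discarded: with
  near-separating gait variables many LOOCV training folds separate, and
  dropping them would corrupt the MR. The held-out subject is classified
  through the (saturated) probability, equivalently the sign of the linear
  predictor; standard errors are suppressed.
* predictors are standardized per training fold (mean/SD of the n−1
  training subjects). This is affine and therefore cannot change any
  classification; it only conditions the solve near separation.

The test suite checks the fitter against closed forms (the saturated 2×2
slope ln 9) and against `stats::glm` fold by fold, and checks MR invariance
under predictor rescaling and row permutation.

## Feature extraction

Curves live on the 101-point grid (0–100% of the gait cycle, inclusive),
the de facto standard in gait analysis. Angle conventions: flexion /
anterior tilt positive in the sagittal plane (X); plantarflexion and
extension extrema are extracted as maxima of the negated curve and reported
as positive magnitudes. Sides are `affected` (paretic; non-dominant in
controls) and `nonaffected`.

Phase windows derive from the gait events of the side under analysis, with
the cycle starting at foot contact: stance `[0, FO]`, swing `(FO, 100]`,
single stance `(OFO, OFC]`, terminal stance `(OFC, FO]`, where FO =
foot-off, OFO/OFC = opposite foot-off/-contact (% of cycle). Event-bounded
windows are half-open on the left so adjacent phases never share a sample;
the partition 1st double support + single support + 2nd double support +
swing = 100% holds exactly by construction. Temporal and spatial symmetry
are defined as affected/non-affected ratios of swing time and step length
(the ratio form; symmetry-index forms exist in the literature, and a ratio
was chosen because it is unit-free, directly interpretable, and consistent
with the side-to-side ROM index).

Deviation scores are control-referenced. The Gait Profile Score is the RMS
over sub-scores, each sub-score the pointwise RMS difference between a
subject's curve and the control mean; the default lower-body set is pelvis
(three planes, once) plus hip (three planes), knee and ankle sagittal for
both sides — 13 curves; the classic 15-curve set also includes bilateral
foot progression, which this container does not carry, and the set is
config-overridable. The Arm Posture Score applies the same functional to
thorax/shoulder/elbow curves. The Gait Deviation Index follows the
feature-space formulation: concatenated curves are projected onto the
orthonormal control basis retaining ≥ 98% of control variance (capped at
n<sub>control</sub> − 1 components), the log Euclidean distance to the
control mean is z-scored against the controls, and the score is 100 − 10z —
so the fitting controls have mean 100 and SD 10 by construction (asserted
to 1e-6 in the suite). An RMS phrasing of the GDI would be the GPS on the
GDI curve set; the feature-space form is the default because it is the
index's defining construction.

Pre-processing: angle time series are filtered with a 15 Hz fourth-order
zero-phase (forward–backward) low-pass Butterworth filter. The
implementation pads with odd reflection over several filter time constants
before `signal::filtfilt`, because zero-initial-condition passes otherwise
leave visible edge transients; the suite verifies unit DC gain and the
squared single-pass magnitude at 1 Hz and 60 Hz (sampling 240 Hz).

Degenerate inputs error loudly and by name: curves that are not 101
samples, unordered events (the offending event is identified), a zero ROM
on the reference side of a ROM index, coincident landmark and centre of
mass in an inclination angle, missing curves in a deviation-score set.

## The synthetic cohort generator

No raw motion-capture data ship with the package, so the generator defines
the study conditions everything is tested under.

**Variable level.** Within each group the variables follow a multivariate
normal with group-specific means and SDs and a shared within-group
correlation matrix (equivalently a Gaussian copula with normal margins —
sufficient for the rank-based downstream analyses; non-normal margins are
deliberately not offered). Group effects are parameterized as stroke-mean
shifts in control-SD units, so effect size is explicit. Defaults:

* group sizes 31/41 and covariate distributions (age 67.3 (10.5) vs
  64.9 (11.5) years; BMI 27.6 (3.9) vs 24.9 (2.3); sex 18/31 vs 21/41 male)
  at the published cohort values, as is gait speed: 0.9 (0.3) m/s stroke vs
  1.3 (0.1) m/s control — note this headline contrast is a 4-control-SD
  shift;
* the remaining 28 defaults are illustrative magnitudes from the
  post-stroke gait literature (full per-variable descriptives were not
  published), with the strongest effects on the headline discriminative
  set: single-support duration, 2nd double-support duration, stride
  length, pelvis sagittal ROM;
* the default correlation is a single-factor model R_ij = λᵢλⱼ (i ≠ j),
  positive semi-definite for any loadings in [−1, 1]. The factor reads as
  overall gait speed/ability: spatiotemporal variables load at |0.7–0.9|,
  reproducing the strong inter-correlation of spatiotemporal parameters in
  real gait data; joint-angle and deviation variables load weakly to
  moderately. A rank-one structure cannot represent several distinct
  correlation cliques — it is the simplest structure that captures the one
  clique that matters downstream.
* `confounded = TRUE` additionally shifts every variable by 0.3 control-SD
  per SD of age/BMI/sex (standardized against the control reference), so
  the groups' covariate imbalance biases unadjusted contrasts and Step-I
  adjustment has real work to do; the suite verifies adjusted screening
  stays near α while unadjusted screening inflates.

**Curve level.** Each subject's curves are built from group template curves
(Fourier series, ≤ 8 harmonics) with a subject-level amplitude deviation
(SD in degrees at the template's peak excursion), pointwise measurement
noise, gait events drawn per group with strict-ordering rejection sampling,
stride time and step lengths per group, and planar CoM/ankle/head tracks
consistent with the subject's step length. Stroke templates on the affected
side scale/offset the control template (reduced knee/ankle excursion,
increased pelvic sagittal range, reduced arm swing, elevated elbow
flexion). One cycle per subject is generated; multi-cycle trials would be
averaged pointwise before extraction.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: non-normal and skewed margins, outliers and
marker artefacts, multiple correlation cliques, within-subject cycle-to-
cycle variability, missing curves, and any coupling between covariates and
curve shape. Tests on synthetic cohorts validate the machinery, not
clinical effect sizes.

## Calibration and the selection effect

Two null calibrations run in the acceptance suite: the Step-I include rate
over 1,000 null screens stays at α = 0.05 (± 1.5 points), and LOOCV with a
single uninformative predictor at group sizes 31/41 drifts to
majority-class prediction, mean MR ≈ 31/72 ≈ 0.43 (± 0.05 over 200 seeds).

The search *minimum*, however, is not a calibrated estimate. With all-noise
candidates the minimum MR over a few hundred subsets falls reliably below
the average single-subset MR (asserted in the suite): the best-of-search MR
is an in-sample-selected quantity and is optimistic for new cohorts, the
more so the more subsets are scored. This matters for interpretation:
screening and search reuse the same subjects by design (mirroring the
analysis this package implements), and no nested selection layer is
offered.

The planted-recovery benchmark makes the flip side concrete. With three
planted variables among 20 candidates the search recovers the planted
triple (it attains the minimal MR, membership judged on the jointly
reported tie group) in ≥ 90% of 100 seeds — but only when the planted
shifts are at the 4-control-SD magnitude of the published gait-speed
contrast. At 2-SD shifts, MR quantization plus selection noise lets some
noise-containing triple strictly beat the true triple in most seeds: at
n = 72, LOOCV MR simply cannot resolve rankings that fine. Recovery claims
for this class of procedure are claims about strong signals.

## Problem sizes and runtime choices

The suite and acceptance script use the study-scale cohort (31/41) for all
statistical checks; moment-convergence checks of the generator use
10,000 subjects per group; curve-level tests use 3–20 subjects per group
(reference fitting requires ≥ 10 controls). The full size-4 search over
~27 screened candidates scores ~21,000 subsets (~1.5 million logistic
fits) in under a minute on one core; the recovery benchmark repeats a
size-3 search over 20 candidates for 100 seeds. Replicate counts (3 cohorts
for the size-profile check, 100/200 seeds for recovery and null
calibration) were chosen as the smallest that make the asserted proportions
stable.

## Known limitations

* MR at threshold 0.5 is the sole criterion, as in the analysis this
  package implements: no AUROC, calibration, or proper scoring rules, and
  no regularized or Bayesian logistic variants.
* Exhaustive enumeration is by design; sizes beyond 4–5 over many
  candidates grow combinatorially and no heuristic search is offered.
* Collinear near-duplicates (gait speed, cadence, stride time…) are not
  pruned a priori; the correlation matrices are provided precisely so users
  can see the redundancy among tied core sets.
* The screening layer offers no robust/nonparametric alternative and no
  FDR control (deliberately, see above).
* Events are inputs: no event detection from kinematics or force plates,
  no inverse kinematics, no marker-level processing.
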