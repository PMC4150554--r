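---
title: "Risk scoring for early adverse cardiac events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk scoring for early adverse cardiac events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macerisk)
```

## The problem

Emergency department chest pain patients span a wide risk range for major
adverse cardiac events (MACE) — death, cardiac arrest, sustained ventricular
tachycardia, or hypotension requiring inotropes or balloon-pump support —
within the first 72 hours. `macerisk` implements a triage-time pipeline that
combines eight routine clinical signs with fifteen heart rate variability
(HRV) parameters derived from a five-minute RR-interval recording:

1. HRV feature extraction (`hrv_profile()` and friends);
2. ensemble variable selection for heavily imbalanced outcomes
   (`select_variables()`);
3. a geometric distance-based 0–100 risk score refined by a calibrated SVM
   (`risk_score()`);
4. clinical comparators — TIMI, MEWS and forward-selection logistic
   regression;
5. an evaluation harness: leave-one-out cross-validation, ROC/AUC with
   DeLong or bootstrap intervals, upper-left-corner cutoffs, nested prefix
   sweeps and paired bootstrap AUC comparison.

No patient-level data ships with the package. A synthetic cohort generator
(`generate_cohort()`) reproduces the group-conditional summary statistics of
the motivating 702-patient cohort (29 events), so every stage is exercised
end to end on data with known ground truth.

## HRV parameters

`hrv_profile()` consumes an `rr_series` (intervals in seconds) that has
normally passed `filter_rr()`, a threshold filter standing in for manual
artifact exclusion: intervals outside [0.3, 2.0] s (30–200 beats/min) or
jumping more than 20% from the previous retained interval are dropped; a
recording with fewer than two surviving intervals is rejected.

*Time domain*: mean and SD of RR (`arr`, `std`); mean and SD of the
instantaneous rate 60/RR (`avhr`, `sdhr`); RMSSD; NN50, the count of
successive-pair differences above 50 ms; and pNN50 = 100·NN50/(n−1), with
the number of successive pairs as denominator. Note `avhr` ≥ 60/`arr` by
convexity, with equality only for constant series.

*Geometric*: the RR histogram uses a fixed bin width, default 1/128 s
(7.8125 ms), the conventional discretization for short-term recordings. The
triangular index is N over the modal bin count. TINN fixes the triangle
apex at the modal bin and exhaustively searches base endpoints (N′, M) over
the histogram bin edges flanking the mode, minimizing the squared error
between the triangle and the bin counts over *all* bins; TINN = M − N′. A
single-occupied-bin histogram returns TINN = 0 by convention — there is no
triangle to fit.

*Frequency domain*: band powers over VLF 0.003–0.04 Hz, LF 0.04–0.15 Hz and
HF 0.15–0.40 Hz, in s². The 0.003 Hz floor is the short-recording
convention — nothing slower is resolvable in five minutes. Because the
tachogram is sampled unevenly (one sample per beat), the default estimator
is the Lomb–Scargle periodogram evaluated directly on beat times, which
avoids resampling distortion; a cubic-spline 4 Hz resampling followed by a
tapered periodogram is selectable (`method = "resample_welch"`). Either
spectrum is rescaled so its integral over the evaluated grid equals the
tachogram variance, making band powers comparable across estimators.
Normalized powers divide by (total − VLF), so `lf_norm + hf_norm = 100`
whenever defined; when the spectrum has no power above the VLF band these
and LF/HF are reported as `NA`, never silently as 0.

## The synthetic cohort generator

`cohort_config()` encodes the study conditions: 702 patients, exactly 29
positive, with group-conditional means/SDs for all 23 candidate predictors
taken from the published group summary table, demographic and
medical-history proportions, and the outcome sub-event composition (9
deaths, 10 cardiac arrests, 8 VT, 16 hypotension, overlapping among the
29 — every positive record carries at least one sub-event and the counts
are exact). Prevalence is exact by construction, not stochastic. Twelve
predictors reported as significant (p < 0.05) form the default
`signal_variables`; all others share the negative-group distribution.

Design choices worth knowing:

* **Truncated normals with moment matching.** Variables are truncated
  normals within physiological bounds (SBP [60, 260], HR [30, 200], SpO2
  [70, 100], ...). Naive truncation biases moments, so the generator solves
  for the underlying (μ, σ) whose *truncated* moments equal the configured
  mean/SD. For pNN50 and NN50 the published SD exceeds what any truncated
  normal on the bounded support can achieve (the family's SD/mean ratio is
  capped); the generator uses the closest achievable distribution.
* **Spectral identities.** LF norm, total power and VLF (unpublished; set
  to the residual of the published band powers) are drawn; HF norm, LF, HF
  and LF/HF are derived so that LF + HF + VLF = total,
  `lf_norm + hf_norm = 100` and LF/HF = LFnorm/HFnorm hold record by
  record. The published table is internally inconsistent as record-level
  identities (its LF/HF mean cannot coexist with its LF and HF means), so
  the derived ratio's marginal is emergent (close to, but not exactly, the
  published one). This is the price of a generator whose records are
  physically coherent.
* **aRR–avHR coupling.** A Gaussian copula with correlation −0.95 ties mean
  RR width to mean instantaneous rate while preserving both marginals; the
  hard identity avHR = 60/aRR would contradict the published pair of
  marginals (Jensen's inequality).
* **Ordinal variables.** GCS is 15 with a small, group-dependent
  probability of depressed values (a tail effect — the published medians
  and IQRs are 15 (15 to 15) in both groups yet the rank test is
  significant); pain is a discretized truncated normal on 0–10.
* **TIMI items.** Item-level rates are not published. Age ≥ 65 derives from
  the drawn age; the other six items are Bernoulli with rates chosen once
  so the implied TIMI discrimination is comparable to the modest
  discrimination reported for TIMI at triage (AUC ≈ 0.64), with a median
  score around 2.
* **RR-series mode.** `mode = "rr_series"` synthesizes a five-minute beat
  sequence per patient — mean level plus LF (0.095 Hz) and HF (0.25 Hz)
  sinusoids plus white noise, amplitudes set from the record's target SD
  and LF/HF balance — and recomputes the HRV columns from the recording via
  `hrv_profile()`, so the extraction code is exercised end to end.

What the generator does **not** emulate: cross-variable correlations other
than the enforced couplings (the published table gives none), missing data,
longitudinal vitals, or realistic ECG morphology. Passing tests therefore
demonstrate the machinery's correctness and the recoverability of the
configured structure — not clinical performance on real patients; the
published real-cohort AUCs are not reproducible without the real data.

## Ensemble variable selection

With 29 events among 702 patients, a single classifier fit is dominated by
the negative class. The selection framework therefore repeatedly draws
*balanced subsets* — all positives plus an equal-size random sample of
negatives without replacement (independent across subsets) — fits a random
forest (default 500 trees; mean-decrease-in-impurity importance by default,
permutation importance selectable) to each standardized subset, and keeps
each forest's top 8 variables. Occurrences are tallied over the default 500
subsets: the tally always sums to `top_k × n_subsets` and no variable can
exceed `n_subsets`. Ties in the occurrence ordering break by mean
within-ranking position, then by fixed column order. The final refinement
removes any top-8 variable whose full-cohort two-sided Mann–Whitney
p-value is ≥ 0.05; an empty survivor set warns rather than failing
silently.

Two statistical caveats, verified empirically in the test suite:

* Conditionally on one fixed cohort, occurrences are *not* uniform under
  the null — the fixed positives' chance separations persist across
  subsets. Exchangeability holds across independent cohorts, which is how
  the null-uniformity test is framed.
* With only 29 positives, replicate cohorts drawn at the published group
  separations yield per-variable significance power of roughly 0.87–0.96
  (the published p ≈ 0.001 corresponds to z ≈ 3.3, so ~10% of replicates
  cross α = 0.05 per variable). Joint recovery of all three leading
  predictors through both stages therefore succeeds in roughly 60–75% of
  replicate cohorts, not near-certainly. The acceptance suite asserts the
  stricter bound and documents the shortfall rather than weakening the
  generator's conditions.

## The distance-based risk score

`risk_score(outcome ~ sbp + avhr + arr, data, lambda = 0.5)` fits, in
order: per-variable min–max bounds mapping the training range onto [−1, 1]
(constant variables are dropped with a warning; test-time values clip to
[−1, 1] so the geometry stays bounded); the two class centroids in the
normalized space; the initial score S0 = 100·d⁻/(d⁺ + d⁻) from the
Euclidean distances to the centroids (50 when both distances vanish); and a
soft-margin SVM refiner — default RBF kernel, γ = 1/p, C = 1, class weights
inverse to class frequency — whose decision values pass through a
Platt-style logistic calibration fitted on the training outputs, giving
S1 = 100·probability. The emitted score is the blend
S = (1−λ)·S0 + λ·S1 clipped to [0, 100]; λ = 0 and λ = 1 reduce exactly to
the pure distance and pure SVM scores. The original scoring system's
fine-tuning step is not fully specified in the source material; the
λ-blend is this package's concrete, parameterized definition of it, with
λ = 0.5 as the default.

Useful properties (all asserted in tests): S0 increases strictly along the
segment from the negative to the positive centroid; scores are invariant
to affine transforms of raw features (normalization absorbs them — for the
RBF refiner because coordinate-wise sign flips preserve distances); every
emitted score lies in [0, 100] for arbitrary inputs. Models persist to
JSON (bounds, centroids, support vectors, dual coefficients, calibration)
and reload without the training data.

## Baselines and evaluation

TIMI is the 0–7 sum of its seven items. MEWS sums banded points on systolic
BP, pulse, respiratory rate, temperature and AVPU consciousness; the band
tables are configuration data (YAML-loadable), defaulting to the common
70/80/100/200 SBP, 40/50/100/110/130 pulse, 9/15/21/30 respiratory, 35/38.5
temperature bands with alert/voice/pain/unresponsive at 0/1/2/3, and GCS
mapping 15 / 13–14 / 9–12 / ≤8 to the four AVPU levels. The forward
logistic baseline adds candidates by smallest likelihood-ratio p while
below the entry threshold (default 0.05, no removal step), with a small
ridge refit as separation fallback.

Evaluation is leave-one-out: the entire pipeline — bounds, centroids, SVM,
calibration — is refitted without the held-out record, which a dedicated
leakage test enforces (training on the held-out point measurably inflates
AUC; the harness must not). The AUC is the rank-based Mann–Whitney
probability with ties at ½ (equal to brute-force pair counting, verified on
hundreds of random instances); its CI defaults to DeLong with a stratified
bootstrap alternative, as the source material does not name its method.
Cutoffs minimize the Euclidean distance to the (0, 1) ROC corner over
midpoint thresholds with ±∞ sentinels, ties resolved toward higher
sensitivity; sensitivity/specificity CIs are Wald — the interval arithmetic
that reproduces the published 69.0–96.5% interval for sensitivity 24/29.
Model pairs are compared by paired class-stratified bootstrap (default 2000
replicates) with a normal-approximation two-sided p on the replicate
difference distribution.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline at the study's
own scale (702 × 29 cohorts) for composition, selection-recovery (ten
cohorts at 100 subsets × 100 trees) and LOOCV comparisons (five cohorts for
the ordering checks), and use smaller two-class tables for machinery
properties; spectral tests use 2–5-minute synthetic tachograms. Exhaustive
enumeration oracles are restricted to combined n ≤ 12 (Mann–Whitney) and
n ≤ 30 (pair-counting AUC). Degenerate inputs resolve by stated convention
rather than error wherever a downstream profile still makes sense:
TINN = 0 on single-bin histograms, undefined spectral indices as `NA`,
p = 1 for identical constant groups, S0 = 50 at coincident centroids.
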