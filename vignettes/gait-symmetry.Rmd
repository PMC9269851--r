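---
title: "Whole-body gait symmetry from trunk acceleration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body gait symmetry from trunk acceleration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsym)
```

## The measurement model

A single inertial sensor worn at the lower back (S1/S2, near the body's
center of mass) records triaxial acceleration at 100 Hz while a person
walks a straight 10 m path. The recorded signal mixes three ingredients:
the gravity component as seen through the (static) sensor tilt, the
periodic whole-body acceleration of gait, and sensor/soft-tissue noise.
The pipeline inverts that mixture step by step:

1. **Low-pass filtering.** A 4th-order Butterworth low-pass at 10 Hz is
   applied forward and backward. Two passes square the magnitude response
   and cancel the phase, so gait features are not shifted in time. Human
   locomotor content at the trunk lives well below 10 Hz.
2. **Tilt estimation and earth-frame rotation.** Over a steady trial the
   periodic components average out, so the mean acceleration vector points
   along gravity. Pitch and roll are recovered from the normalized mean;
   the inverse rotation (an isometry) aligns the vertical axis with
   gravity, and the static vector (0, 0, g), g = 9.81 m/s², is
   subtracted. This assumes the sensor does not migrate during a trial and
   that the trial contains at least two full strides.
3. **AP extraction.** The symmetry analysis uses only the
   anterior-posterior component; mediolateral acceleration is kept solely
   to attribute sides, and vertical acceleration only as context.
4. **Initial-contact detection.** Contacts appear as prominent positive AP
   peaks. The detector first reads the dominant step rate off the AP power
   spectrum (a peak must exceed 10× the median in-band power, else a
   "no gait detected" error), then accepts local maxima above
   `median + k·MAD` (k = 1) separated by at least 0.35 step periods,
   resolving conflicts in favour of the taller peak, and finally refines
   each peak to sub-sample precision with a quadratic fit through its
   neighbours. Sub-sample refinement matters: at 100 Hz a one-sample
   rounding of a contact rotates the two sides' cycle windows against
   each other and visibly biases the correlation.
5. **Side attribution.** The trunk sways toward the stance side, so the
   sign of the mean mediolateral acceleration in a ±50 ms window around a
   contact indicates its side (positive = right by default; the convention
   is a configuration entry). Strict left/right alternation is enforced by
   flipping the weaker-evidence member of any same-side pair. If every
   window mean is below the noise floor the trial errors ("sides
   indeterminate") rather than guessing.
6. **Cycles, normalization, side means.** A gait cycle (stride) runs from
   a contact to the next ipsilateral contact as a half-open interval.
   Durations outside [0.6, 2.5] s — slower or faster than plausible human
   strides — are dropped with a logged reason. Each cycle is linearly
   interpolated onto P = 101 points (the field's percent-of-cycle grid;
   point k sits at k/P of the cycle, so the first point is the contact
   sample), and cycles are averaged pointwise per side.

The **Symmetry Index** maps the Pearson correlation r between the two
side-mean waveforms onto a 0–100 scale: SI = (r + 1) × 100 / 2. It is
invariant to positive affine transforms of either waveform and symmetric
in the sides; correlations overshooting |r| = 1 by more than 1e-12 are an
error, smaller overshoot is clamped.

**Walking speed** is path length divided by trial duration. Because speed
(unlike the SI) correlates with body size, each observed speed is divided
by the value predicted from weight (kg) and height (cm) under an OLS
regression with intercept, fitted once per speed condition: conditions
differ systematically in speed, so pooling them would confound the
normalization. The within-condition mean of the normalized speed is ~1 by
the OLS residual property.

## The synthetic cohort generator

No public recordings accompany this kind of protocol, so the package
ships a generator with exact ground truth; every downstream stage is
validated against it.

A trial is built from `n_strides` strides, each two steps (left then
right). Within a step of phase φ ∈ [0, 1) the stride phase is
(k + φ)/2, k ∈ {0, 1}. Each axis is a short harmonic series in stride
phase (orders are multiples of the stride frequency):

* AP: orders 2 and 4 (amplitudes 1.0 and 0.4 m/s²) — i.e. step-periodic.
  In symmetric gait the trunk's AP acceleration repeats every *step*; only
  asymmetry introduces odd (stride-frequency) content. This is also forced
  by the symmetric limit: if the symmetric AP signal carried a stride-
  frequency fundamental, the left- and right-anchored cycle waveforms
  would be phase-shifted copies and r < 1 even at zero asymmetry.
* ML: orders 1 and 3 (0.6, 0.1 m/s²) — the sway alternates with the
  stance side, phased so the trunk leans toward the stance side around
  each contact.
* V: orders 2 and 4 (1.5, 0.3 m/s²) — dominated by twice the stride
  frequency, as in real lumbar recordings.

The AP phases place the contact peak mid-step (φ ≈ 0.55), so the first
and last contacts of a trial sit a few tens of samples inside the trace,
clear of the filter's edge-settling zone.

**Asymmetry injection.** One knob α ∈ [0, 1] modulates alternate steps,
in amplitude (scale 1 ± α), in timing (a shift of α·π/8 radians of step
phase), or both. The modulation is applied through a C¹ envelope that is
zero at the step boundaries and exactly 1 on a plateau covering the
contact peak: this keeps the signal continuous (an abruptly scaled step
would introduce jump discontinuities that ring through the low-pass
filter and exist in no real gait), while the peak modulation remains
exactly 1 ± α, so the per-cycle peak ratio right/left is
(1 − α)/(1 + α) in closed form. Under amplitude asymmetry the side-mean
correlation is approximately (1 − α²)/(1 + α²): α = 0.15 corresponds to
SI ≈ 97.6 and α = 0.28 to SI ≈ 93 under the default noise.

**Stochastic components.** Stride times are jittered with a lognormal-free
Gaussian CV (default 0.02, floored at 0.2× the nominal duration); white
Gaussian sensor noise (default 0.3 m/s² per axis) is added in the sensor
frame; a static tilt (pitch/roll) rotates the earth-frame signal into the
sensor frame. Ground truth records every contact time and side (contacts
are defined at the noiseless AP peak of each step), the exact noiseless
AP waveform of every cycle on the 101-point grid, and the true mean
speed.

**Cohort design.** Seven age groups (6–12 up to 71–84 years; sizes 19,
20, 20, 20, 20, 20, 18 — 137 participants) with group-specific
weight/height means and SDs; draws are truncated at ±3 SD and at
physiologic floors (10 kg, 90 cm). Three speed conditions share the
walkway: stride frequencies 0.75/0.90/1.05 Hz and target speeds
0.80/1.15/1.55 m/s (Slow/Comfortable/Fast), with three trials each.
Individual speed scales linearly with height (plus a 4% lognormal
residual) and cadence inversely with its square root, so walking speed —
but not the SI — depends on anthropometry. The per-group-and-condition
asymmetry profile defaults to a 0.15 baseline everywhere, elevated to
0.28 in the Fast condition for Children, Teenagers, Middle-Aged, Senior
and Elderly; through the α→SI mapping this reproduces the qualitative
study pattern (group mean SI from ≈97.6 down to ≈93 in Fast for affected
groups) with Young Adults and Adults flat across conditions. A
per-participant lognormal multiplier (CV 0.15) on α supplies
between-subject variance. All randomness derives from one master seed via
per-participant and per-trial hashed streams, so results are independent
of evaluation order and bit-reproducible.

**What the generator does not emulate:** turning or gait initiation and
termination, dynamic (per-sample) sensor re-orientation, soft-tissue
artifact structure, arrhythmic or pathological gait, and any
gyroscope/magnetometer channel. Tests passing on this generator show the
*pipeline* is correct under its stated signal model, not that the model
captures every property of real recordings.

## The statistical battery

* **Assumption checks**: Shapiro–Wilk per condition, Levene's test with
  the classical mean center (median optional).
* **Split-plot ANOVA**: age group (between) × speed condition (within),
  decomposed in the two classical strata via `aov` error strata with
  sequential sums of squares (groups here are at most mildly unbalanced).
  Sphericity is handled by the Greenhouse–Geisser ε computed with Box's
  formula from the pooled within-group covariance of the condition
  columns, projected on an orthonormal contrast basis; ε multiplies both
  numerator and denominator degrees of freedom of the within-stratum
  tests. ε is clamped to its theoretical range [1/(k−1), 1] and equals 1
  exactly at k = 2.
* **Post hocs**: all pairwise t tests (pooled-variance between groups,
  paired between conditions), Bonferroni-adjusted as min(1, m·p) with m
  the declared family size (21 group pairs; 3 condition pairs).
* **Canonical LDA** per condition on (SI, normalized speed): the
  between/within scatter generalized eigenproblem solved through a
  Cholesky-symmetrized form; per-function variance proportions from the
  eigenvalues; Wilks' Λ for functions j..J as Π 1/(1+λ); Bartlett's χ²
  approximation for significance; the structure matrix as pooled
  within-group correlations between the features and the discriminant
  scores (scores scaled to unit pooled within-group variance; equal
  priors). The normalized (not raw) speed enters the LDA, matching the
  variable actually analysed after normalization.

## Numerical choices and degenerate inputs

* Filter edges: odd-reflection padding with each pass offset by its edge
  value, so DC passes exactly and a constant trace filters to itself to
  1e-9. Edge transients still contaminate roughly the first and last
  half second; the generator keeps true contacts out of that zone, and on
  real data the walkway lead-in serves the same purpose.
* Zero-SS effects in ANOVA report F = 0, p = 1 instead of 0/0 noise; the
  threshold is relative (1e-12 of the total SS).
* The LDA within-scatter receives a relative ridge (1e-8 of the mean
  within variance) so a perfectly separating zero-within-variance feature
  yields the degenerate limit (100% of discriminating variance, loading
  ±1) instead of a failure; a feature constant overall still errors by
  name. All within-group moments (score scaling, structure matrix) use
  the ridged scatter consistently.
* Aggregation of the three trials per condition: arithmetic mean of trial
  SIs (the smallest-variance unbiased combiner absent other guidance); a
  "pool-cycles" strategy — pool all normalized cycles, then one SI — is
  available by configuration and coincides with the mean in the noiseless
  symmetric limit.
* Trials with fewer than 5 total cycles warn and carry a QC flag rather
  than erroring, so short fixtures remain usable while the quality rule
  stays visible in outputs.
* Side-label ties (two consecutive same-sign contacts) flip the weaker
  event; the detector breaks peak conflicts by height. Both rules are
  deterministic.
* The symmetric limit SI = 100 is exact (to 1e-9) when the stride period
  is an integer number of samples, because both sides then sample
  identical intra-cycle phases and interpolation error cancels; at
  incommensurate stride frequencies the limit holds to about 1e-3 SI
  units, which is far below every effect of interest here.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: the
analytic two-pass Butterworth magnitude (with the bilinear-transform
prewarped frequency axis — the correct analytic response of a digital
filter near the Nyquist rate), closed-form interpolation error bounds,
generator ground truth for detection (recall/precision and timing over
100 seeded noisy trials), explicit QR-projection sums of squares for the
split-plot ANOVA, a closed-form 2×2 generalized eigensolver for the LDA,
and a straight-line re-computation of the SI from the filtered noiseless
signal at the true contact times (agreeing with the pipeline to about
1e-4 SI units across the asymmetry grid).

Monte-Carlo checks use deliberately reduced designs chosen once: type-I
calibration of the Greenhouse–Geisser-corrected interaction runs 1000
replicate null cohorts of 4 age groups × 8 participants, one trial per
condition on a 6 m path (rejection rate within 3–7% at α = 0.05);
pattern recovery runs 100 replicate 7-group × 4-participant cohorts with
the default asymmetry profile (interaction detected in ≥80%, with the
affected groups' SI dropping in Fast while Young Adults/Adults stay
flat). The anthropometric correlation check uses the full 137-participant
design and evaluates correlations within age groups, since group
membership shifts both body size and gait.

## Limitations

The event detector is a documented AP-peak rule, not the proprietary
algorithm of any commercial gait software; absolute SI values from other
toolchains may differ slightly even on identical signals. Tilt correction
is static — a sensor that rotates mid-trial violates the model. The
statistics assume complete repeated measures (incomplete participants are
removed listwise, loudly). Reported group-level F, Λ and loading values
from real cohorts cannot be reproduced here because no raw recordings are
publicly available; the package instead guarantees the machinery is
correct on signals whose truth is known.
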