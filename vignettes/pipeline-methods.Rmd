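---
title: "Methods: decoding game demand and pain from fNIRS and heart rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding game demand and pain from fNIRS and heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A neuroadaptive game needs an implicit, real-time readout of how engaged a
player is and, in a clinical setting, whether they are in pain. `gamenirs`
implements an end-to-end analysis for that question: eight midline fNIRS
channels (two sources at Fz and CPz, separations 2.85-3.90 cm, 761/847 nm,
10 Hz) plus heart rate are turned into windowed features and used to classify
two binary states — game demand (Easy vs Hard) and cold-pressor pain
(pain vs no-pain) — with participant-independent models.

Because no recordings are distributed with the package, a synthetic cohort
generator with full ground truth stands in for human data. Every processing
stage is therefore testable: we know exactly what activation, artifacts and
heart-rate responses were injected, and can verify what comes out.

## The synthetic cohort

`sim_config()` fixes the study conditions. Each of 20 participants plays four
~180-s games (Easy/Hard crossed with pain/no-pain, order counterbalanced by a
Latin square) and additionally contributes a 90-s rest baseline and a no-game
cold-pressor session.

**Cortical activation.** Each game session's HbO course is
`amplitude * (0.3 * tonic + 0.7 * phasic)`, where the tonic part is the game
boxcar and the phasic part a Poisson train of discrete gameplay events
(default 6 per minute) — overtakes, collisions, near-misses — both convolved
with a double-gamma HRF whose peak is at 7 s (undershoot ratio 1:6, 32-s
support) and normalised to unit peak. The split matters: a sustained 180-s
boxcar is almost entirely removed by the 0.01-Hz high-pass edge, so the
event-driven component is what carries class information through the analysis
band. `amplitude` is 0.6 µM for Easy and 1.0 µM for Hard (a 0.4 µM demand
effect), values in the range reported for prefrontal activation during
demanding tasks.

**Nuisance structure.** Cardiac (1.1 Hz, 0.05 µM), respiratory (0.25 Hz,
0.08 µM) and Mayer-wave (0.1 Hz, 0.12 µM) oscillations with random phases per
channel, white noise (0.1 µM), and a slow linear drift (±0.003 µM/s). With
these defaults the noise surviving the 0.01-0.09 Hz band has sd ≈ 0.08 µM,
comparable to the 0.4 µM demand effect after the same filtering (in-band
signal sd ≈ 0.07 µM per unit amplitude) — so the demand contrast is present
but not trivially separable, and activation recovery sits around r ≈ 0.75.
HbR is `-0.5 * HbO` plus independent noise (0.03 µM), reflecting the
anti-correlated physiology that CBSI assumes.

**Motion.** Artifacts arrive at ~1/min; each is a 0.5-2 s optical-density
step (equivalent to a 5 µM HbO excursion) injected *after* the forward
Beer-Lambert step, strictly inside a simultaneous 0.5-g accelerometer burst.
Ground truth records every segment.

**Heart rate** is synthesised directly as a smooth bpm series (resting level
N(70, 5) per session, +2 bpm during play, +3 bpm more under Hard demand,
+8 bpm during immersion, respiratory sinus arrhythmia and smoothed
variability). A template-train ECG synthesiser exists only to exercise the
R-peak extractor.

**Tolerance durations.** Immersion times are right-censored log-normal,
censored at the 180-s protocol cap. `calibrate_truncated_mean()` profiles the
censored-mean equation: for any sigma the mean constraint pins mu (the
censored mean is monotone in mu), and sigma is then chosen to match the
censored sd. The defaults reproduce observed censored means (sds) of 22.5
(9.75) s with no game, 48.5 (35.73) s during Easy and 74.07 (64.11) s during
Hard play. Matching the Hard sd of 64 s forces sigma ≈ 1.42, so very short
immersions (a few seconds) are legitimate draws — the pipeline must cope with
pain sessions that yield zero analysis windows.

**Reproducibility.** Each (participant, condition) session has its own seed
derived from the master seed, so a session is bit-reproducible and
independent of cohort size.

What the generator does **not** emulate: scalp/systemic physiology shared
across channels beyond the three oscillators, skin-conductance-style slow
confounds correlated with the task, optode coupling changes that drift rather
than step, HRF variability across cortex, or any true coupling between pain
and cortical haemodynamics (pain only moves heart rate). Passing tests
therefore demonstrate internal consistency of the pipeline under its own
assumptions, not classifier performance on real recordings.

## Preprocessing

Stages run in a fixed order — mBLL inversion, band-pass, motion correction,
CBSI — recorded in provenance flags; calling a stage out of order is an
error.

1. **mBLL inversion.** Optical-density changes are converted to HbO/HbR by
   solving the per-sample 2x2 system with molar extinction coefficients
   interpolated from the standard compiled haemoglobin tables (Gratzer/Cope)
   at 761/847 nm, channel separations from the montage, and DPF 6.0
   (configurable; the conventional adult value).
2. **Band-pass.** Chebyshev Type I, overall order 6, 0.5 dB ripple,
   0.01-0.09 Hz edges, applied forward-backward. Zero-phase filtering uses
   steady-state initial conditions plus odd reflection padding; without the
   initial-condition handling, constant input leaves ~0.5 residuals at the
   edges, with it the DC residual is below 1e-9. The double pass squares the
   magnitude response (passband gain at 0.05 Hz ≈ 0.90, stopband attenuation
   at 1 Hz far beyond 40 dB).
3. **Motion correction.** Movement is flagged only where *both* streams
   agree: the moving sd (MSD) of the gravity-removed accelerometer magnitude
   (512 Hz, resampled to 10 Hz by windowed RMS) and the MSD of the
   channel-mean fNIRS signal each exceed mean + 2 sd of their own session
   MSD. Exceedance masks are dilated by 1 s before the conjunction, and
   segments closer than 1 s are merged. Detection runs on the *unfiltered*
   concentrations, where steps are still sharp; the zero-phase band-pass
   smears a step over roughly ±10 s, which would both hide it from an MSD
   detector and defeat segment-wise reconstruction. Corrected segments are
   widened by 3 s (covering ~85% of the smeared artifact energy) and
   reconstructed by linear interpolation between 2-s pre/post baseline means;
   an edge segment uses its single available baseline.
4. **CBSI.** With `alpha = sd(HbO)/sd(HbR)` per channel,
   `HbO' = (HbO - alpha*HbR)/2` and `HbR' = -HbO'/alpha`, rendering the pair
   perfectly anti-correlated. Only HbO' feeds the feature extractor.

Heart rate comes either from the recording's HR stream or from raw ECG via a
generic extractor (5-20 Hz band-pass, adaptive threshold at 60% of the 99th
amplitude percentile, 0.3-s refractory period, RR outside [0.3, 2] s
discarded, 60/RR interpolated to 10 Hz). The institution-specific artifact
pipeline used for the original recordings is out of scope.

## Features

Game intervals are cut into consecutive 8-s windows; a trailing partial
window is kept if it covers at least 4 s, so a 180-s game yields 22 full
windows plus a 4-s remainder = 23 epochs. Per epoch:

- 8 channels x {mean, peak, adjusted Fisher-Pearson skewness (0 for a flat
  window), unbiased variance, trapezoidal AUC of the signed signal in µM·s}
  = 40 HbO statistics;
- 28 channel pairs x {Pearson correlation, wavelet coherence} = 56
  connectivity features;
- 6 heart-rate statistics {mean, median, max, min, range, sd}.

**Wavelet coherence.** Analytic Morlet (ω₀ = 6), 12 voices per octave,
smoothed in time by a Gaussian matched to each scale (applied in the
frequency domain) and across scale by a 0.6-octave boxcar — without
smoothing, coherence is identically 1. Coherence is averaged over
0.08-0.3125 Hz, a band that cannot be resolved inside an isolated 8-s
window (12.5-s period at the low edge), so the transform runs on the full
game-length series and the time-scale map is averaged within each window.
Points inside the cone of influence (edge distance < √2·scale) are excluded;
a window that lies entirely inside the cone — only the trailing partial
window can — falls back to the unmasked band mean rather than going missing.

## Datasets, balancing, selection

Three tasks: demand (Easy vs Hard, full games of all four conditions), and
pain vs no-pain within each demand level. For the pain tasks both sessions of
a participant are truncated to the first T seconds of the game, T being that
participant's immersion duration (immersion starts with the game countdown),
so the classes span equal wall-clock time by construction. SMOTE (synthetic
points on segments between minority nearest neighbours, k = 5, gap uniform in
(0,1)) is applied only when a *training* partition's class ratio exceeds 1.1,
and only inside the cross-validation loop — balancing before the split would
leak synthetic neighbours of test points into training.

ReliefF runs as a deterministic full pass (every sample is a reference; no
sampling seed to document), with Manhattan distances on internally min-max
normalised features and prior-weighted misses. k follows the square-root
rule (rounded half-even, bumped to odd): k = 3 for the 6 heart-rate features.
For the 96-column fNIRS stream the rule would give 11; the pipeline instead
exposes an explicit override defaulting to 15, the value used in practice for
fNIRS feature sets of this design — it is not derivable from the stated rule,
so it is configuration, not computation. The cut-off on the sorted weight
curve is the point of maximum perpendicular distance from the chord joining
the first and last weight; the features strictly *above* that elbow are kept
(the elbow itself is the first point of the flat tail — this convention, and
not "keep through the elbow", reproduces the intended selections on worked
examples). A collinear curve has no elbow; all positive-weight features are
kept.

## Classification and evaluation

`nested_cv()` repeats ten times: participants are split 60/40 (all windows of
a participant on one side), ReliefF selection, z-scoring and any SMOTE are
fitted on the training side only, and each algorithm is tuned by an inner
10-fold grid search on the training rows before refitting and scoring on the
untouched test rows. A leakage guard snapshots the test rows before
selection/tuning and verifies them bit-identical afterwards. Grids: SVM
(radial) cost {0.1, 1, 10, 100} x gamma {0.001, 0.01, 0.1, 1}; kNN
k {3, 5, ..., 15}; random forest 500 trees, mtry {√p, p/3, p/2}; naive Bayes
is deliberately untuned. Inner selection maximises mean accuracy with ties
going to the simpler model (grids are ordered simple to complex). Metrics:
accuracy, F1, TPR, TNR, and AUC by trapezoidal ROC integration, with
Hard/pain as the positive class; aggregates are mean (sd) over repeats.

Accuracy is compared against the binomial corrected chance level: the
smallest k with CDF(k; n, 1/2) ≥ 0.95, divided by n. At the conventional
printed sample sizes this is 0.54 (n = 400) and 0.5625 (n = 160);
`nested_cv()` also reports thresholds at the realised test sizes. The
original analysis compared fold accuracies to chance by ANOVA; that is
replaced here by the direct threshold comparison, which is the quantity the
ANOVA was probing.

## Numerical and design choices

- Coordinates are stored in mm, separations reported in cm, display rounding
  half-even to 2 decimals. One tabulated montage separation (channel 2,
  3.02 cm) disagrees with its own printed coordinates (3.0025 cm); the loader
  keeps the recomputed value and warns.
- The CSV dialect prints doubles with 17 significant digits, making
  write-then-read bit-exact; SNIRF round trips are float-exact only.
- Events are half-open `[start, end)` intervals in seconds from stream
  origin.
- Filter edge cases: series shorter than 3x the filter order cannot be
  zero-phase filtered and raise an error rather than returning garbage.
- `elbow_cutoff` treats a maximum chord distance below 1e-9 as collinear.
- Degenerate CV splits (a single-class training side) are resampled with a
  shifted, logged seed.
- Zero-variance windows produce NA Pearson correlations with a warning
  (a flat window should degrade one feature, not the epoch).

## Problem sizes used by the test-suite

Unit tests run on single sessions or purpose-built toy matrices. The
calibration checks use cohorts of 20 participants with the two no-pain game
conditions, SVM only with a 2x2 grid and 5 outer repeats, and ten replicate
cohorts for the null condition; tolerance-model checks use 100,000 draws.
These sizes were chosen as the smallest at which the binomial chance band is
meaningfully narrow while a cohort remains cheap to simulate.

## Known limitations

- Group-wise holdout with ~8 test participants makes per-repeat accuracy
  cluster at the session level; the binomial band treats windows as
  independent and is therefore optimistic. This is visible in null-cohort
  calibration, where occasional cohorts fall slightly below the band.
- The wavelet-coherence smoothing operator (Gaussian + 0.6-octave boxcar) is
  one of several reasonable choices; coherence values are comparable only
  within a fixed smoothing convention.
- The AMARA-style detector's windows and thresholds are this package's
  defaults (the published parameterisation is not reproduced) and are logged
  with every run.
- Pain affects only heart rate in the generator; fNIRS-based pain
  classification on synthetic cohorts is expected to sit at chance, which
  mirrors the original study's empirical result but is an assumption here,
  not a finding.
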