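---
title: "Localizing outflow-tract arrhythmia origin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing outflow-tract arrhythmia origin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Premature ventricular complexes (PVCs) and ventricular tachycardia arising
from the ventricular outflow tracts are routinely cured by catheter
ablation, but the operator must decide whether to start mapping in the
right (RVOT) or left (LVOT) outflow tract. The 12-lead surface ECG carries
that information: a right-sided origin activates the septum left-to-right
and produces a left-bundle-branch-block-like, net-negative QRS in lead V1
with a late precordial R/S transition, while a left-sided origin produces
an early transition or a dominant V1 R wave. `otloc` implements a complete
pipeline that turns one sinus-rhythm (SR) beat and one PVC beat per patient
into an RVOT/LVOT call, together with the classical single-criterion
predictors used as baselines, and a synthetic 12-lead generator that serves
as the test substrate for every stage.

## Pipeline overview

1. **I/O and rate normalization** — records are read from CSV or a minimal
   WFDB (format 16) reader, matched case-insensitively to the canonical
   lead order, and resampled to 2,000 Hz by FFT (band-limited)
   interpolation. All indices in the package are 0-based and windows are
   half-open `[start, stop)`.
2. **Denoising** — per-lead periodized discrete wavelet transform with the
   30-tap coiflet-5 filter; soft thresholding of detail coefficients by
   Stein's unbiased risk estimate (SURE); the coarsest approximation is
   zeroed to remove baseline wander.
3. **Windowing** — the beat reference is the sample of maximum absolute V6
   voltage within ±50 ms of the annotation. Windows are 215 samples either
   side of the reference for SR beats (430 total) and 335 for PVCs (670
   total): the class-wise mean QRS duration plus four standard deviations,
   so essentially every QRS fits.
4. **Automated morphology features** — every interior local extremum of
   every lead segment is measured (location, prominence, distances to the
   two prominence boundaries, width at half prominence, boundary span,
   amplitude versus the zero baseline, contour height). Eight extrema per
   lead per beat (the one closest to the reference, three before, four
   after, zero-padded when absent) give a 192 × 8 matrix, expanded into
   604,416 raw/ratio/difference features.
5. **Conventional features** — Q/R/S amplitudes and durations per lead
   from a deflection-threshold QRS delineator, twelve published
   localization indices/criteria, and a 104,529-feature ratio expansion.
6. **Model** — gradient-boosted trees (binary logistic loss) on either
   feature set; features with non-zero Shapley (TreeSHAP) attribution are
   retained and the model refitted; the decision threshold is chosen on
   the validation ROC by Youden's J; RVOT is the positive class and a
   score exactly at the threshold classifies RVOT.
7. **Evaluation** — accuracy, sensitivity, specificity, F1 and rank-based
   AUC, percentile-bootstrap CIs (20,000 replications by default), DeLong
   (midrank) AUC confidence intervals, and the paired DeLong test for
   comparing the two extractors.

## Key measurement definitions

The prominence of a peak is the vertical drop from the peak to its lowest
enclosing contour line: scan left and right to the nearest strictly higher
sample (or the window edge); the prominence bases are the minimal samples
in those stretches (nearest the peak on ties) and the prominence is the
peak height minus the higher of the two minima. Valleys are measured
identically on the negated signal. Width is measured where the signal
crosses `peak - prominence/2`, linearly interpolated between samples and
bounded by the bases. These definitions agree with the brute-force contour
oracle in the test suite on every random signal tried, and (for
calibration) with the conventions of widely used signal-processing
libraries.

Two definitional points were genuinely ambiguous and are resolved as
follows:

* *Amplitude and contour height.* Amplitude is the extremum voltage
  relative to the zero (isoelectric-corrected) baseline; contour height is
  computed literally as `prominence - amplitude` and may be negative. For
  a peak rising straight from baseline the two cancel, which is the only
  reading that makes the pair self-consistent.
* *Matrix columns.* The extractor records eight numeric measurements plus
  a peak/valley flag; the matrix is 192 × 8, so the flag is carried as
  descriptor metadata rather than a ninth column.

### The expansion recipe

The exact pair-enumeration behind the original 1,600,800-feature count is
defined only in supplementary material not available here, so the package
fixes its own documented recipe and exposes it as the single place to
swap: raw cells; all ordered within-row (cross-measurement) ratios; all
ordered within-column (cross-extremum) ratios and differences; and
SR-over-PVC same-lead same-slot cross-measurement ratios. Total 604,416,
constant across inputs. Ratios with a zero denominator are defined as 0 so
zero-padded slots cannot poison the vector. The conventional expansion
uses all-pairs ordered ratios over its 24 × 13 measurement table because
the reported top conventional features are cross-lead *and*
cross-measurement (e.g. an R amplitude in lead III against an R amplitude
referenced to the S-wave offset in V1).

## Denoising choices

The wander band is 0–0.5 Hz, so the decomposition depth defaults to 11 at
2 kHz: the zeroed coarsest approximation then covers < 0.49 Hz. An earlier
draft used depth 8 (approximation < 4 Hz); that removed genuine ST/T
energy and measurably *increased* the error against clean templates, so it
was rejected. Shrinkage is applied to detail levels 1–8 only (above ~4 Hz,
where power-line interference and wideband noise live), with a per-level
median-absolute-deviation noise scale — a single finest-level estimate
cannot see 50 Hz interference, which lives around level 5. The SURE
threshold includes the standard sparse-case guard that falls back to the
universal threshold. On a noiseless band-limited beat train the per-sample
distortion of the full chain stays below 0.08 mV (regression-locked).
A 50 Hz IIR notch is available behind `notch_50hz` but off by default,
matching the wavelet-only framing.

## Conventional measurements and criteria

The isoelectric baseline is the median of the first 40 ms of the window (a
T-P-segment stand-in). QRS onset is the earliest deflection of more than
0.02 mV from baseline sustained for at least 4 ms, offset symmetric from
the right; both constants are exposed as arguments because no numeric
criterion is published. Waves are baseline-crossing lobes: R is the lobe
with the maximal positive deflection, Q the deepest negative lobe before
it, S the deepest after; monophasic negative complexes follow the QS
convention (all amplitude in S, R and Q exactly zero). Secondary positive
deflections (RsR') are not measured separately — the automated extractor
covers them.

The transition-zone score is V1 = 1 … V6 = 6, first lead with R/S > 1; a
lead with R and S equal within a 5% band scores half a step later
(transition falling between that lead and the next). Percentage R wave is
`R/(R+S)` by amplitude, the only quantity this protocol measures. Records
that never transition give a missing score, and every criterion that needs
an undefined index returns `indeterminate` rather than a silent zero. All
twelve reproducible published criteria are kept in an auditable registry
table with their thresholds applied boundary-inclusively exactly as
printed (a V2 transition ratio of exactly 0.6 predicts LVOT). The
composite score `Y = -1.15 TZ - 0.494 (V2S/V3R)` is published without its
decision cutoff; the registry uses −4, the approximate midpoint of the
class-conditional means in the synthetic world, and records the choice
here.

## Model choices

The booster is implemented in C++ with exact greedy splits, no
subsampling and no random number use, so training is deterministic by
construction. Hyperparameters (depth 4, 200 rounds, learning rate 0.1, L2
1.0, early stopping on validation AUC after 50 stale rounds) are invented
defaults — the source protocol names none — and live in `gbt_params()`.
Feature retention uses exact path-dependent TreeSHAP (verified against an
exhaustive Shapley enumeration on small trees and additive to the margin
on full ensembles) with a 1e-12 floor on mean absolute attribution. One
selection pass is performed; the loop count is configurable in principle
but a single pass already collapses the feature set to the informative
core. "Optimal discretization cutoff" is operationalized as Youden's J on
the validation ROC with candidate cutoffs midway between adjacent distinct
scores; ties resolve toward 0.5, and an all-tied score vector yields 0.5
with a warning rather than an error.

Because the booster is written from scratch rather than taken from a
large-scale library, inputs wider than `max_screen` (default 3,000)
columns are first reduced by a univariate screen — absolute standardized
mean difference between classes, computed on the training split only. The
pipeline streams the 604,416-wide expansion through this screen one
record at a time, so the full design matrix is never materialized. This
is a capacity compromise the original GPU-scale setup did not need; the
screen is deliberately simple, deterministic, and applied before any
model-based selection.

## The synthetic world

`generate_record()` builds sum-of-Gaussians beats (P, R, S, T waves; PVCs
wide, premature at 85% of the sinus RR interval, without a preceding P and
with discordant T). The precordial R/S amplitude ratio is log-linear in
the lead index and crosses 1 at the configured transition lead: sinus
beats default to 3.5 (normal), RVOT PVCs to 4.5 (late, V1 net negative),
LVOT PVCs to 2.0 (early). Limb leads carry a fixed inferior-axis profile.
Noise defaults — 0.05 mV power-line, 0.2 mV sub-0.5 Hz wander, 0.02 mV
white — are typical clinical magnitudes. Cohorts are 77% RVOT, matching
the reported prevalence, with per-record jitter: lead gains and per-lead
R/S balance ±20%, transition ±0.5 lead, QRS durations across their stated
ranges (sinus 70–110 ms, PVC 120–180 ms), heart rate 60–90 bpm, noise
scales ×0.5–1.5. The log-ratio slope of the precordial progression
(`transition_slope`, default 0.7) was calibrated once so that, under this
jitter, most single criteria sit roughly in the 70–95% accuracy band while
the full model exceeds them — qualitatively mirroring the published
comparison — and then frozen. One caveat is structural: because the
generator is required to encode RVOT as a transition at or beyond V4 and
LVOT at or before V2, the pure transition-zone criterion is perfect *by
construction* in this world and no model can strictly beat it; the
corresponding test therefore asserts dominance over the clear majority of
criteria and their mean, not over every one.

What the generator does **not** emulate: axis pathology, atrial
fibrillation, conduction disease beyond the PVC morphology itself,
electrode misplacement, or the sub-site structure under each outflow
tract. A green end-to-end test therefore establishes that the pipeline
recovers a latent class encoded in precordial morphology under realistic
noise — not clinical-grade performance on real patients, which would
require the original (optional, downloadable) clinical dataset.

## Evaluation conventions

The headline F1 is the positive-class (RVOT) F1: the published value is
reproducible from the implied test confusion matrix only under that
reading (the prevalence-weighted macro variant gives ≈97.7, not the
printed 98.46); macro and weighted variants are emitted alongside.
Bootstrap intervals are percentile (not BCa), 20,000 replications by
default, with single-class resamples skipped and counted. The DeLong
variance uses the midrank formulation and equals the O(n²) pairwise
kernel exactly on every instance tried; the CI is a normal approximation
clipped to [0, 100]. Percentages are rounded to two decimals for
reporting.

## Limitations

* The expansion recipe and several numeric constants (QRS deflection
  threshold, refinement radius, booster hyperparameters, the Y-score
  cutoff) are documented package choices, not published values.
* The univariate pre-screen could in principle discard a feature that is
  informative only in interaction; the synthetic world shows no such loss,
  but wider screens are a one-line configuration change.
* Real-data performance claims are out of scope; nothing in the test suite
  depends on the clinical dataset.
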