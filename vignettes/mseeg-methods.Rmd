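---
title: "Methods: multiscale entropy of infant EEG and parent alternating gaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale entropy of infant EEG and parent alternating gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

`mseeg` implements, as tested and reusable code, an analysis linking a
parent's attention-orienting behavior to the complexity of their infant's
neural response. Infants view short videos of two children playing together
(joint play) or side by side (parallel play) while 32-channel EEG is
recorded; separately, a free-play interaction is video-coded for *parent
alternating gaze* — the parent looking at the infant, then at an object,
then back. Neural complexity is quantified with multiscale sample entropy
(MSE) of the preprocessed EEG, and a general linear model asks whether
infants of parents who alternate gaze more show higher entropy.

No public dataset accompanies this design, so the package ships a synthetic
cohort generator with a ground-truth manifest; every stage of the pipeline
is validated against that ground truth, against exhaustive oracles, or
against closed-form values.

## Preprocessing chain

The chain and its defaults (all in `pipeline_config()`):

1. **Resample** 5000 Hz acquisitions to 500 Hz. Multistage FIR decimation:
   each stage low-passes with a linear-phase kernel (Hamming design, unit DC
   gain, zero net delay) whose stopband protects the final 0–250 Hz band,
   then decimates. Events are remapped to the nearest new sample.
2. **Band-pass 0.1–100 Hz** on the continuous data, before epoching, so
   filter transients never sit at epoch edges. The 0.1 Hz edge uses a
   second-order Butterworth applied forward–backward (an equivalent FIR
   would need tens of seconds of kernel); the 100 Hz edge is a
   delay-compensated FIR (transition width `min(0.25·f_hi, Nyquist − f_hi)`).
3. **Line noise**: within consecutive 4-s windows, each channel is regressed
   on a sine/cosine pair at 60 Hz and the fitted sinusoid subtracted.
   Windowing tracks slow amplitude drift; only the projection onto the line
   frequency is removed, so broadband neighbors are untouched.
4. **Epochs**: sixteen consecutive non-overlapping 1-s epochs per 16-s
   trial, labeled with the trial's condition. Truncated trials yield
   `absent` epochs and a warning.
5. **Bad channels**: a channel whose peak absolute amplitude exceeds 500 μV
   in more than 50% of epochs is replaced by spherical-spline interpolation
   (stiffness 4, 50 Legendre terms) on an idealized unit head sphere. The
   montage ships as package data; positions are the geometric 10–20
   construction (arc midpoints by spherical interpolation), not digitized
   coordinates. If more than 25% of channels are bad the subject is flagged
   unusable instead.
6. **Epoch rejection**: an epoch is discarded when any channel's sample SD
   within any 200-ms window exceeds 80 μV. The window slides by 100 ms (50%
   overlap, with a final flush to the epoch end); the published rule fixes
   only the window length, so the hop is our choice.
7. **Average reference** across all scalp channels.
8. **GFP selection**: per condition, the 10 epochs whose *total global field
   power* (per-sample spatial SD, summed over the epoch) lies closest to the
   condition median are selected, so every subject contributes the same
   amount of data to the entropy estimate. Fewer than 10 clean epochs in
   either condition excludes the subject. "Trials" in the selection rule is
   read as 1-s epochs; selection at the video level is available via
   configuration. Ties break by temporal order; the median of an even count
   is the midpoint of the central pair. Summing rather than averaging the
   spatial SD changes no ranking.

The stage order (interpolation on epoched data, before rejection) follows
the published description as printed.

## Modified multiscale sample entropy

Sample entropy of a series is
`SampEn(m, r) = −ln(A / B)`, where `B` counts pairs of length-`m` templates
whose Chebyshev distance is at most the tolerance, and `A` counts the same
pairs still matching when extended to length `m + 1`. We use `m = 2`,
`r = 0.5`, natural log (nats), non-strict `≤` matching (stated because
strict and non-strict differ at ties), and the Richman–Moorman convention
that only the first `L − m` template positions of a length-`L` segment are
used, so `A ≤ B` and entropy is non-negative by construction.

Two modifications matter:

* **Discontinuous segments.** The selected data are 1-s epochs, not one
  continuous record. Templates never span an epoch boundary, but template
  *pairs* are compared across all epochs and the counts `A`, `B` are pooled
  before the log ratio — one estimate per subject × condition × channel ×
  scale, with the counts returned for audit.
* **Per-scale tolerance.** The scale-`s` series is the mean of consecutive
  non-overlapping `s`-sample blocks. Coarse-graining shrinks variance, so a
  tolerance fixed at the scale-1 SD conflates variance reduction with
  regularity. We recompute the tolerance at every scale as `r` times the SD
  of the pooled coarse-grained points (pooled across the subject-condition's
  selected epochs, not per epoch — a per-segment tolerance would break count
  pooling). The test suite demonstrates the signature: white noise gives a
  flat entropy curve under the per-scale tolerance and a decaying curve
  under the fixed one.

Cells with `A = 0` or `B = 0` (undefined log ratio), zero pooled SD, or too
few coarse-grained points are marked invalid and excluded — never
zero-filled — from downstream means; cell counts are reported.

**Scale–frequency mapping.** The analysis averages entropy over scales
"within 3–8 Hz", but the correspondence between a coarse-graining factor
`s` and a frequency is conventional. The default takes scale `s` at rate
`f_s` to track fluctuations at `rate / s` (scales 63–166 at 500 Hz); the
alternative reads a block as half a period, `rate / (2s)` (scales 32–83).
Both are implemented (`scales_for_band()`); the choice is a configuration
switch. At the largest scales a 500-sample epoch contributes only 3 points;
pooling across the 10 selected epochs keeps the counts usable, and per-cell
counts are reported rather than capping the scale range.

Entropy within the band scales is averaged over the channels of five
regions of interest — left frontal (Fp1, F3), right frontal (Fp2, F4), left
central (FC1, C3), right central (FC2, C4), and all remaining scalp
channels as a comparison region.

The pair counting is compiled code (sorted by first template coordinate so
only first-coordinate matches are examined); its contract is *exact* count
agreement with a naive O(n²) enumeration oracle, asserted on dozens of
random instances in the test suite, plus an analytic anchor: for Gaussian
white noise with `m = 2`, `r = 0.5`, consecutive-match probabilities are
independent, so SampEn → `−ln erf(0.25) ≈ 1.286`.

## Parent alternating gaze

From a coded event log (onset, offset, target ∈ infant/object/other), the
metric is the total duration of infant→object→infant sequences in which
each constituent look lasts at most 2 s, after discarding the first minute
(acclimation) and merging abutting same-target looks so coder segmentation
cannot affect the score. Overlapping chains (I-O-I-O-I…) credit each look's
time once. The 2-s rule has a second defensible reading — every I-O-I triple
qualifies but each look is credited at most 2 s — implemented behind
`cap_mode = "credit"`; the default treats the cap as a qualification
criterion because it modifies what counts as alternating gaze, not the
credited time. Neither reading is asserted as the original coders'.

Inter-rater reliability is ICC(2,1): two-way random effects, single rater,
absolute agreement, computed from the ANOVA mean squares with the standard
F-based confidence interval. The published analysis names only the model
family; the (2,1) form is the conventional choice for that description.

## The general linear model

Rows are subject × condition × ROI. The response is the square root of the
band/ROI entropy (variance-stabilizing, for normally distributed
residuals); parent gaze is z-scored across subjects; viewing condition and
ROI enter as treatment-coded covariates with reference levels *parallel*
and *other*. Estimation is ordinary least squares — deliberately ignoring
the repeated measures within subject, mirroring the original analysis; a
subject-clustered (CR0) standard-error option exists for sensitivity
checks, and the cohort-level null-recovery test uses that interval, because
the plain OLS interval undercovers by construction when rows are correlated
within subject.

Screening follows the published order: rows with internally studentized
residuals above 3 in absolute value are removed and the model refit once
("median standardized residuals" as printed is not a standard diagnostic;
we read it as the studentized-residual rule). Cook's distances are computed
on the refit; rows with D > 1 are reported, not removed. More than 5% of
rows removed raises a hard warning (that is misfit, not outliers).

Post-hoc ROI comparisons are estimated marginal means at `gaze_z = 0`,
averaged over condition, with Tukey-adjusted pairwise contrasts (the
emmeans default).

## The synthetic cohort and what it does (not) emulate

Each subject's EEG is 32 channels at 5000 Hz: per channel, a unit-variance
mixture of 1/f noise (spectral shaping of white noise, exponent 1) and
white noise weighted by an irregularity parameter `c ∈ [0.15, 0.9]`, scaled
to 25 μV RMS, plus a shared 6-Hz oscillation (mid-band for this age group)
weighted toward frontal/central channels so the ROI structure is
non-trivial. Trials follow the acquisition design: 16 videos of 16 s,
conditions pseudorandomized with no condition three times in a row.
Ground-truth artifacts are injected exactly where the manifest says:
200-ms, 25-Hz bursts (300 μV) on the 100-ms grid for epoch rejection, an
8-Hz 800 μV sinusoid on one channel in 60% of epochs for interpolation, and
overloaded subjects (120 contaminated epochs in one condition) for the
exclusion rule. Gaze logs are built so the alternating-gaze metric equals a
target `a + b·c + ε` by construction, with filler looks inside the
discarded first minute.

Translating a requested pipeline-level gaze coefficient into the slope `b`
requires the empirical slope κ of sqrt band-ROI entropy on `c` through the
whole chain, because preprocessing and band-scale coarse-graining attenuate
the raw association. `analysis/00_calibrate.R` measures κ; the shipped
default (`pipeline_config()$entropy_per_c = 0.040`, measured over 26
full-pipeline subjects) implies a ceiling of about 0.009 for the
coefficient — the same order as published estimates, i.e. the band-scale
association is intrinsically weak. `generate_cohort(effect = "max")`
removes gaze noise entirely (gaze an affine function of `c`) for recovery
tests at that ceiling.

What the generator does **not** emulate: volume conduction or any head
model (channel noise is independent; only the oscillation is shared),
ocular or movement artifacts with realistic morphology, eye-tracking-gated
stimulus timing, infant behavioral states, or coder disagreement beyond
boundary jitter. Passing tests therefore show the *pipeline* is faithful to
its stated rules and recovers known structure — not that the biological
effect would replicate.

## Numerical choices and problem sizes

* Filters: Hamming-window FIR, order `⌈3.3 · rate / transition⌉` rounded
  even, renormalized to unit DC gain; reflection padding; compiled direct
  convolution for short kernels, FFT convolution otherwise.
* Line regression windows shorter than two line-frequency cycles are
  skipped.
* GFP ties break by temporal order; selection is stable and reproducible.
* Entropy counts are exact integers (stored as doubles; counts can exceed
  2³¹); no tolerance is applied to the counts themselves.
* Degenerate inputs (constant signals, empty logs, single-coder tables,
  zero-SD gaze) are rejected or flagged invalid rather than imputed.
* Test problem sizes: oracle instances ≤ 60 samples (exhaustive
  enumeration stays exact and fast); the analytic white-noise check uses
  10⁵ points; curve-shape checks 200 × 500-sample epochs; statistical
  calibration 500 null and 200 effect tables at n = 61 subjects;
  end-to-end cohorts 12 subjects at full acquisition fidelity (5000 Hz,
  16 × 16 s), which one CPU processes in a few minutes.

## Known limitations

* OLS on repeated measures mirrors the original analysis; its nominal
  p-values are anti-conservative under within-subject correlation. Use the
  cluster-robust option for inference you intend to trust.
* Idealized spherical montage positions; interpolation quality on a real
  cap depends on digitized coordinates.
* Only the multiplexed IEEE float32 BrainVision dialect is read or
  written; other layouts fail loudly by design.
* The scale↔frequency mapping is a convention; results for narrow bands
  can differ between the two implemented rules.
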