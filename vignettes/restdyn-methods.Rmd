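---
title: "Methods: multiscale entropy, spectral power and task PLS for resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale entropy, spectral power and task PLS for resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restdyn)
```

# Overview

`restdyn` analyses resting-state EEG in repeated-measures group designs
(e.g. two age groups, each measured before and after a training
intervention). Three stages are chained:

1. **Preprocessing** — segmentation of continuous recordings into fixed
   epochs, peak-to-peak amplitude rejection, channel subsetting.
2. **Feature extraction** — multiscale sample entropy (MSE) or normalized
   spectral power density (SPD) per channel, averaged over epochs, giving
   one channel-by-feature grid per subject and condition.
3. **Inference** — mean-centered task partial least squares (PLS) over the
   grids, with permutation tests for latent-variable significance and
   bootstrap ratios for the stability of the feature saliences.

A seeded synthetic-EEG generator reproduces the statistical structure of
such a study, so the whole pipeline can be exercised, calibrated and
power-checked without any recordings.

# Preprocessing

Continuous multichannel data (EDF, the package's epoched container, or a
CSV fallback) are band-pass filtered (linear-phase FIR, default
0.5–40 Hz), then cut into contiguous, non-overlapping, left-aligned epochs
(default 2500 ms; a 2-minute resting block at 1000 Hz yields 48 epochs).
Windows are sample-indexed, 0-based and half-open, which removes
off-by-one ambiguity in the segmentation round-trip.

An epoch is rejected when **any** channel's within-epoch max minus min
exceeds the threshold (default 100 µV; stimulus-locked pipelines
conventionally use 80 µV). The criterion could also be read as a global
field measure; the per-channel-any reading matches common practice and is
the one implemented. Rejection is applied **before** channel subsetting,
so rejected-epoch counts refer to whole-montage epochs; rejecting after
subsetting would not commute and is deliberately not the pipeline order.

Independent-component artifact removal (ocular, muscle, cardiac) is an
upstream responsibility: the package expects already-cleaned data.

# Multiscale entropy

For scales $s = 1, 2, \dots$ the series is coarse-grained by averaging
non-overlapping windows of length $s$ (scale 1 is the original series).
Sample entropy of each coarse-grained series is

$$\mathrm{SampEn}(m, r) = -\ln\frac{A}{B},$$

where $B$ counts pairs of length-$m$ templates within Chebyshev distance
$r$ (self-matches excluded, pairs over $i<j$, templates drawn from the
first $N-m$ positions for both lengths) and $A$ counts the same pairs
still matching when extended by one sample. Defaults are $m = 2$ and
$r = 0.5 \times \mathrm{SD}$, with scales limited to those retaining at
least 50 coarse samples — for 2500-sample epochs, scales 1–50.

Numerical conventions that matter and are fixed by tests:

* **Tolerance convention.** $r$ is computed from the **original
  (scale-1)** series SD, per channel and per epoch, and reused at every
  scale. Recomputing the SD per scale would systematically inflate
  coarse-scale entropy. A per-recording SD would be the other defensible
  choice; per-epoch was chosen because epochs are the unit of averaging,
  and the convention is documented here as a deliberate switch.
* **SD normalizer.** Population ($1/N$); at $N = 2500$ the difference
  from $1/(N-1)$ is negligible, but oracle tests need one fixed choice.
* **Undefined estimates.** When $A$ or $B$ is zero the estimate is
  undefined; `NaN` is returned with a warning and the epoch average skips
  such cells (recorded in `nEpochsAveraged`). Dropping cells is less
  biased than clamping to an arbitrary ceiling.

The compiled counting kernel is checked against a brute-force pure-R
enumerator on hundreds of random series, and against the analytic iid
Gaussian limit $-\ln(2\Phi(r/(\sigma\sqrt2))-1) \approx 1.287$ at
$r = 0.5\sigma$.

# Spectral power density

Each epoch is z-normalized (mean 0, population SD 1) — removing global
amplitude differences between groups — and Fourier-transformed without
taper or padding, so 2500 samples at 1000 Hz give exactly 0.4 Hz bins.
Relative power is each bin's share of total power over the analysis range
(default 0.4–40 Hz: the 0 Hz bin is zeroed by mean removal, and 40 Hz is
the filter edge). Band shares sum bins whose centers fall in closed
intervals: delta 1–3, theta 4–7, low composite 1–7, alpha 8–14, beta
15–30, gamma 30–40 Hz. The 7→8 and 14→15 Hz gaps are preserved rather
than merged, and gamma is capped at the recording band edge; all edges are
parameters of `defaultBands()` rather than constants.

# Mean-centered task PLS

Subject grids are flattened into a rows-by-features matrix, rows ordered
subjects-within-conditions-within-groups. The cell-mean deviation matrix
$M$ (one row per group-by-condition cell, minus the unweighted grand mean
of cell means) is decomposed by SVD, $M = USV^\top$: each latent variable
pairs a design contrast ($u_k$, the design saliences) with a brain pattern
($v_k$, the feature saliences) at covariance strength $s_k$.

* **Sign convention.** The SVD sign is fixed by flipping each $v_k$ so its
  largest-magnitude element is positive (design saliences flip jointly);
  maps are therefore reproducible. Contrast-specific orientation (e.g.
  "post minus pre in the trained group") is applied by the caller from
  the design saliences.
* **Permutation test.** Whole subjects (all their condition rows) are
  reassigned across groups without replacement and condition labels are
  shuffled within subject, respecting the repeated-measures structure.
  Permuted singular values are compared LV-by-LV by rank by default; a
  Procrustes mode (rotating the permuted decomposition onto the original
  before comparison) is available for toolbox parity, as the original
  description does not state which was used. $p$-values use the add-one
  estimator $(1 + \#\{s^{perm}_k \ge s_k\})/(1 + n_{perm})$ and are never
  exactly zero.
* **Bootstrap ratios.** Subjects are resampled with replacement within
  group (carrying all their conditions). Each bootstrap's feature
  saliences are aligned to the original — orthogonal Procrustes rotation
  by default, per-LV sign alignment as the lighter alternative — before
  accumulating the standard error; this is the one place rotation is
  required, since unaligned sign flips inflate the SE to meaninglessness.
  The bootstrap ratio is the original salience over that SE; $|$ratio$|
  \ge 2$ is the conventional stability threshold (roughly a 95% interval),
  exposed as a parameter. Zero-SE elements yield `NaN` with a logged
  count.

Study defaults are 500 permutations and 500 bootstrap samples. The same
engine accepts entropy grids (channels × timescales), power grids
(channels × frequency bins) and event-related-potential grids (channels ×
timepoints) — the electrode-selection analyses reuse it unchanged.

# The synthetic generator

Each generated epoch is a $1/f^\alpha$ background (frequency-domain
shaping of white Gaussian noise — exact slope control at $O(n\log n)$),
plus band-limited Gaussian oscillations (Gaussian spectral envelopes with
stated center and FWHM bandwidth, amplitudes relative to the unit-SD
background), plus white measurement noise. A configurable fraction of
epochs receives a one-cycle sinusoidal transient whose peak-to-peak
amplitude is set by the profile; the affected epoch indices are recorded
so rejection can be audited exactly. Epochs are generated independently by
default (decoupling stage tests from segmentation); a continuous signal
can be produced for segmentation tests by concatenation.

Randomness is a strict seed hierarchy (study seed → subject seed → epoch
seed), so the full dataset is bit-reproducible and any single recording
can be regenerated in isolation. Subject identity is preserved across
conditions by drawing each subject's band-amplitude scaling factors
(Gaussian, mean 1, SD 10%) once and applying them to every condition's
profile — making group inference nontrivial but recoverable, as in a
repeated-measures design.

**Default profiles.** No generative model for real aging EEG exists in
the analysis itself, so the profile parameters are tuning targets chosen
once, by spectral reasoning, and not revisited: the *young* profile uses
a steep background ($\alpha = 1.6$) with prominent delta/theta
(5 Hz component) activity; the *old* profile a flatter background
($\alpha = 1.0$) with relatively stronger beta (20 Hz). A flatter
spectrum is whiter at short lags, so the old profile yields higher
fine-scale and lower coarse-scale entropy plus a larger beta share — the
canonical aging signature. The background SD defaults to 5 µV, placing
clean-epoch peak-to-peak amplitudes (roughly 40–70 µV including the
oscillatory components) clearly below the 100 µV rejection criterion, so
that — as in real recordings, where only a small fraction of resting
epochs is rejected — rejection removes injected transients, not the
background. The *trained* (post-training) profile steepens
the background by 0.35 and raises the 3–14 Hz component amplitudes by
50%, producing the training signature: more coarse-scale entropy and more
low-frequency power.

**What the generator does not emulate:** volume conduction and electrode
geometry (channels are statistically independent), biophysically shaped
artifacts (transients are generic), nonstationarity within a recording,
and genuinely nonlinear dynamics — its entropy differences are driven
entirely by spectral shape. Passing recovery tests therefore demonstrates
that the pipeline detects effects of the stated size under clean,
stationary, linear-Gaussian conditions; it does not certify performance
on real recordings.

# Problem sizes and calibration choices

The simulation suites run at deliberately reduced sizes chosen to keep
the Monte-Carlo noise small relative to the margins being tested:

* **Null calibration:** 200 replicate null studies (2 × 2 design, 6
  subjects/group, 2 channels, 2 epochs of 2000 ms at 250 Hz), 99
  permutations each. The empirical rejection rate at $\alpha = 0.05$ must
  fall in $[0.02, 0.09]$.
* **Effect recovery:** 20 replicate studies per scenario (8
  subjects/group, 4 channels, 2 epochs of 2500 ms at 1000 Hz, 99
  permutations, 50 bootstraps), requiring significant LV1 with the
  injected direction pattern in at least 80% of replicates.
* Generator defaults remain at study scale (48 epochs, 2500 ms, 1000 Hz,
  the 35-channel montage with the 20-channel analysis subset).

With the default effect sizes the injected contrasts are strong, so the
80% recovery requirement is comfortably met at these sizes; the tests are
regression guards on direction and calibration, not power analyses.

# Degenerate inputs and edge rules

* Constant series: normalization errors out (SPD); entropy tolerance
  $r = 0$ is undefined, so the channel yields `NaN` at all scales with a
  warning (MSE).
* All epochs rejected: an explicit error — downstream stages never
  silently receive zero epochs.
* Rank-deficient $M$: trailing singular values below
  $\max(\dim M)\,\epsilon\,s_1$ are dropped; with identical cells one LV
  with $s \approx 0$ remains.
* `nPerm < 19` warns that $\alpha = 0.05$ cannot be resolved.
* Sampling-rate/epoch mismatches (`epochMs * fs / 1000` non-integer) are
  validity errors, not silent truncations.

# Known limitations

* MSE at coarse scales uses few samples (50 at scale 50) and is noisy;
  the minimum-samples rule bounds, but does not remove, this variance.
* The permutation scheme assumes subjects exchangeable across groups
  under the null; covariate-stratified permutation is not implemented.
* Bootstrap SEs with very small groups (< 5 subjects) are themselves
  unstable; the bootstrap-ratio threshold is approximate, not a
  calibrated test.
* No correction across latent variables or features is applied; the
  original method argues saliences are estimated in a single step, and
  the package takes no stance beyond exposing the threshold.
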