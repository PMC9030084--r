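---
title: "Methods: stride segmentation, gait-phase division and fused stride-length estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride segmentation, gait-phase division and fused stride-length estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstride)
```

This vignette is the package's account of its methods: the models and the
assumptions behind them, the tunable parameters and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the numerical decisions a maintainer would otherwise have to reverse-engineer
from the code.

## Data model and conventions

A foot-mounted IMU recording is a uniformly sampled 6-channel stream
(3-axis accelerometer, 3-axis gyroscope). Because device mounting differs
between datasets — and descriptions of which physical axis is "vertical"
are notoriously inconsistent — every algorithm addresses channels through
anatomical *roles* (coronal = left-right, sagittal = anterior-posterior,
vertical = gravity-aligned) via an explicit `channel_map`, never through raw
axis names.

All sample indices in the public API are 0-based and all intervals half-open
`[start, end)`. This makes phase tiling exact (`[a,b)` and `[b,c)` tile
`[a,c)` with no gap or overlap) and keeps IoU arithmetic free of off-by-one
ambiguity. Acceleration units are metadata, never assumed: the algorithms
are scale-aware only through *relative* thresholds. Gravity is not removed;
the stance-phase vertical acceleration is expected to sit near +g, and the
volatility statistics used for stance detection are location-invariant
before squaring, scale-relative after.

## Stride segmentation: subsequence DTW with start propagation

A stride template of length $L$ is built by linearly resampling reference
strides to $L$ samples and averaging column-wise. Averaging across subjects
and speeds yields a smooth, speed-neutral prototype; $L$ defaults to the
median input stride length.

Matching does not compare raw samples. Each sample $i$ is described by its
neighborhood over $i \pm w$ (replication-padded): the mean gradient
$(x_{i+w}-x_{i-w})/2w$, the amplitude range, and the window mean (a Haar
coefficient variant is available behind the configuration). Descriptor
distance is Euclidean. Smoothing the local distance this way keeps the
accumulated-distance curve smooth and monotone along paths, which the match
extraction relies on. With `normalize = TRUE` each sequence's descriptors
are divided by that sequence's amplitude range, making the detected
boundaries invariant to rescaling the stream by any positive constant.

The recurrence uses unweighted steps $\{(1,1),(1,0),(0,1)\}$; every cell
stores both the minimal accumulated distance and the stream column where its
path entered template row 0 (start propagation, as in streaming subsequence
matching). At the final template row this yields, per path end, an
accumulated distance and a start. Match extraction is threshold-free:

* one candidate per start group — the end minimizing the accumulated
  distance (ties to the earliest end, so zero-cost extensions through quiet
  samples do not inflate a match);
* candidates shorter than $L/3$ are suppressed (a terminal half-stride is
  about $L/2$, so it survives; single-peak noise does not);
* candidates are accepted greedily by ascending distance; a candidate
  overlapping an accepted match is a *competitor*: it is dropped if its end
  lies within $L/2$ of the accepted end (a rival alignment of the same
  stride) or if the overlap exceeds $L/4$; smaller overlaps — boundary
  jitter between adjacent strides — are trimmed away, and the reported
  warping path is trimmed with the interval.

Quiet regions never produce spurious matches because every path end in a
quiet region is owned (via start propagation) by the preceding genuine
stride, whose zero-cost extension is always cheaper than aligning the whole
template against silence.

The matched channel defaults to the coronal gyroscope, where the swing
rotation of the foot gives the most template-like periodicity; this is
configurable.

## Gait-phase division by major peak-valley pairs

A stride decomposes into push-off, swing, heel-strike and stance, in that
order, with stance closing the cycle. The two dynamic boundaries —
push-off/swing (toe-off) and swing/heel-strike (heel contact) — are abrupt
changes of the foot-ground force. On the sagittal and vertical acceleration
they appear as a dominant peak followed by a valley with a zero crossing in
between; everything else in the cycle is comparatively quiet.

**Preprocessing.** Both channels pass a moving mean (default 5 samples,
50 ms at 100 Hz — wide enough to suppress sensor noise, narrow enough not
to blur a 50 ms force transient), then are deflated by sign-preserving
squaring $y = \mathrm{sign}(m)\,m^2$, which stretches dynamic excursions
relative to the near-zero stance.

**Stance detection.** A short window (25 ms, at least 3 samples, odd)
slides over both preprocessed channels; a position qualifies as static when
the windowed variance and IQR fall below stride-relative thresholds
(defaults: 2 % of the stride-wide variance, 10 % of the stride-wide IQR —
relative, because absolute thresholds fail across walking speeds). Under
noise the qualifying positions inside the true stance fragment, and a
momentary swing lull can qualify while the true stance does not, so the
detector (a) ignores the last few window positions, which the mean filter's
replication padding flattens artificially, (b) merges qualifying fragments
separated by gaps of at most 10 % of the stride, (c) requires the chosen
cluster to reach near the stride end — stance closes the cycle — and
(d) progressively widens the thresholds (×1, ×2, ×4, ×8) until such a
cluster exists. If nothing ever qualifies the stride is reported as "no
stance found". The stance returned for phase tiling runs from the detected
begin to the stride end.

**Extrema clustering.** Peaks and valleys (strict local extrema with
prominence at least 5 % of the preprocessed signal range; plateaus count
once at their first index) between the previous stance end and the upcoming
stance begin are split by a deterministic 1-D 2-means whose centers are
initialized at those two bounds; assignment uses squared distance with ties
going left, and iteration stops after 50 rounds or a center shift below
0.5 samples. The left cluster carries push-off evidence, the right cluster
heel-strike evidence. Both peaks and valleys enter the clustering by
default (`cluster_peaks_only` switches to peaks only).

**Major peak-valley pair.** Within a cluster, each peak pairs with the
nearest *following* valley — the morphology is a towering peak decaying
through zero into a trough. Pairs must cross zero; the largest span wins. A
secondary crossing pair with span above half the major span and its peak
within 5 samples of the major valley merges into one pair spanning (first
peak, second valley); this stabilizes the pair when noise splits one force
transient in two. The pair's peak may follow its valley past the cluster's
right edge, so a cluster boundary falling inside a pair cannot orphan it.
If no crossing pair exists the largest-span pair is used with a warning.

**Boundary fusion.** Two-reference mode: push-off/swing is the rounded mean
of the sagittal peak and the vertical valley; swing/heel-strike of the two
peaks. Four-reference mode adds the derivative zero crossings nearest the
respective extrema (negative crossings correspond to peaks, positive to
valleys; the derivative is the first difference with trailing replication)
and applies leave-one-out outlier rejection before averaging: a reference
farther than 3 SD from the mean of the others is dropped. Rejection is
skipped below 4 references (the SD of 2 points is degenerate) and never
empties the set. Rounding is half-away-from-zero. The fused boundaries must
satisfy `stride start < b1 < b2 < stance begin`; otherwise the stride is
reported in the diagnostics — never silently dropped.

## Stride-length estimation

Per dynamic phase, the default 12 features are the classical empirical
step-length terms evaluated on three channels (sagittal, vertical, and the
per-sample magnitude of the 3-axis acceleration): the Weinberg term
$(a_{max}-a_{min})^{1/4}$, the Kim term $(\sum_i |a_i|/N)^{1/3}$, the
variance, and the range. Cadence (strides/s) and Scarlett's normalized mean
$(1/N)\sum_i (|a_i|-a_{min})/(a_{max}-a_{min})$ are available behind
configuration flags but off by default, keeping the audited feature count
at 12; flat channels yield 0 for the Weinberg and Scarlett terms instead of
an error. The multiplicative constants of the original empirical models are
absorbed by the regressor.

Training per phase: random-forest importances (impurity-based, normalized
to sum 1, seeded; 300 trees) select features above an importance share of
0.05 — a cut that keeps the handful of informative terms and discards the
long tail, with a fallback to the single top feature; the selected columns
are standardized to zero mean and unit unbiased SD (zero-variance columns
are dropped and recorded); then an SVR with RBF kernel is fitted
(`C = 10`, `epsilon = 0.01`, `gamma = 1/p` on standardized features — a
mid-range cost that tolerates the centimetre-scale label noise without
underfitting). `svr_adaboost` wraps the same base learner in AdaBoost.R2
(30 estimators, linear loss, weighted resampling, weighted-median
combination), which trades runtime for robustness to heavy-tailed
residuals. A whole-stride model is trained identically on full-stride
features for comparison. All randomness is seeded; training and prediction
are bitwise-reproducible given the seed.

Prediction fuses the three per-phase estimates by their arithmetic mean —
deliberately the simplest fusion; a stride missing a phase (segmentation
failure) is predicted from the remaining phases and flagged as partial.
Estimates carry the unit of the training references.

## Evaluation metrics

Predicted and labeled segments are matched greedily one-to-one by
descending IoU; any overlap counts as a true positive by default
(`min_iou = 0`), configurable to stricter cuts such as 0.5. Precision,
recall and F-score follow the standard definitions with the convention that
all three are 0 when there are no true positives. Temporal IoU divides the
overlap length by the *spanning* interval `max(end) − min(start)` — for
overlapping intervals identical to the true set union; for disjoint
intervals the ratio is 0 anyway because the intersection is empty. RMSE is
reported in the reference unit, and the relative distance error compares
the accumulated estimates against an independently measured path distance,
in percent, signed.

## The synthetic generator

`generate_walk()` emulates the per-phase morphology of walking acceleration
at the foot with piecewise raised-cosine kernels (versioned constants —
changing them invalidates frozen test values):

* push-off: a loading dip on the sagittal channel and a gravity-to-zero
  rotation ramp on the vertical channel, ending in the toe-off transient —
  a planted major peak-valley pair per channel with a zero crossing: the
  sagittal peak and the vertical valley sit exactly on the push-off/swing
  boundary;
* swing: quiet (sagittal near 0, vertical near +g), ending in the
  heel-impact transient whose sagittal and vertical peaks sit on the
  swing/heel-strike boundary;
* heel-strike: rapid decay with a vertical sub-peak in its second half
  (the forefoot slap);
* stance: the static values (0, 0, +g) for the final 30 % of the cycle.

Phase durations are fixed at 20 / 35 / 15 / 30 % of the cycle — typical
proportions for self-selected walking. Kernel amplitude grows linearly with
cadence (`8 + 12·cadence` m/s² for acceleration, `80 + 160·cadence` deg/s
for the gyroscope), reproducing the speed–magnitude relation of real foot
signals; slow/middle/fast self-selected speeds correspond to cadences of
about 0.7/0.9/1.1 strides/s at the default 100 Hz sampling rate. Noise is
white Gaussian with SD expressed as a fraction of the per-stride amplitude.
The coronal gyroscope carries a stride-periodic bump train (push-off and
swing rotations) used for template matching. True stride lengths come from
a declared `length_map` — by default affine in the vertical Weinberg term,
`1.0 · weinberg − 1.1` m, giving realistic 1.4–1.6 m strides — plus
Gaussian noise (default SD 3 cm); the map is carried in the configuration
so parameter-recovery tests are self-describing. An optional terminal
half-stride is the first half of the kernel followed by quiescence (with a
5-sample fade), annotated as a stride of half the usual displacement and
without phase labels.

What the generator does **not** emulate: drift and bias of real IMUs,
inter-stride morphology variation beyond amplitude/duration scaling,
double-support asymmetries, turning, running or backward gait, and
non-Gaussian impact noise. Tests passing on this generator therefore show
that the algorithms recover what the model plants under controlled noise —
not that they reach any particular accuracy on real recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by choice, at the sizes the
methods are meant to handle while staying quick to execute: stride matching
on a 100-stride variable-speed walk (~11,500 samples) plus brute-force DTW
oracle comparisons on ~150-sample streams; phase segmentation on 50-stride
walks at three cadences and two noise levels; length-model training on 500
strides across a 10-cadence grid with a 125-stride held-out split, and a
cadence-shift experiment training at 0.7 and 1.1 strides/s and testing at
0.9. The DTW recurrence is compiled (Rcpp); everything else is plain R.

Tie-breaks and degenerate inputs are fixed as follows: DTW predecessor ties
prefer diagonal, then vertical; extrema plateaus take their first index;
k-means assignment ties go to the left cluster; fused boundaries round
half-away-from-zero; equal-distance candidate matches keep the earlier end;
a flat feature channel yields 0 rather than 0/0; standardization drops
zero-variance columns; outlier rejection never empties the reference set.

## Known limitations

* Stance/swing confusion is the dominant failure mode at high noise: both
  are quiet, so the volatility statistics separate them only through the
  end-anchoring heuristic, and the stance IoU degrades (the dynamic
  boundaries stay accurate). Fast walking shortens the stance and
  aggravates this — an adaptive-threshold stance detector is the natural
  next step.
* The IoU union is the spanning interval by definition; a strict set-union
  variant would differ only for disjoint pairs, where the ratio is 0
  either way.
* Boosted SVR (AdaBoost.R2) is implemented in-package; its resampling makes
  it the slower option and it only pays off with outlier-contaminated
  references.
* The detected stride boundaries from matching jitter by a few samples;
  when segmentation then fails on a truncated stride, the pipeline flags it
  (partial fusion or NA) rather than guessing.
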