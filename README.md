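# gaitstride

Stride segmentation, gait-phase division and stride-length estimation from
foot-mounted IMU recordings.

Pedestrian dead reckoning (PDR) accumulates per-stride length and heading to
track position where GPS is unavailable. Its weakest link is the stride-length
model: empirical regressions (Weinberg, Kim, Scarlett, Ladetto) treat each
stride as a single block and need per-user recalibration, because the signal
features they use change with walking speed and individual gait habits.
`gaitstride` implements a phase-aware alternative for researchers and
engineers working with foot-mounted inertial sensors:

1. **Threshold-free stride segmentation (SDATW).** A stride template —
   the column mean of many strides linearly resampled to a common length
   `L` — is matched against the continuous stream by subsequence dynamic
   time warping over per-sample *neighborhood descriptors* (mean gradient,
   amplitude range, window mean over `i±w`). Each cell of the
   accumulated-distance matrix also propagates the stream index where its
   warping path entered the first template row, so every path end knows its
   start; matches are emitted where the accumulated distance at the final
   template row is minimal among all path ends sharing a start, and
   candidates are compared only against overlapping local competitors —
   no absolute distance threshold anywhere. This keeps truncated terminal
   "half-strides" (a bout's last, roughly half-length stride) detectable.

2. **Gait-phase division by major peak-valley pairs.** Each stride is split
   into push-off, swing, heel-strike and stance. The sagittal and vertical
   accelerations are mean-filtered and signed-squared
   (`y = sign(m)·m²`); the stance is the quiet terminal segment whose
   windowed variance and interquartile range fall below stride-relative
   thresholds. Extrema between two stances are clustered by a
   deterministic 1-D 2-means (centers initialized at the stance
   boundaries); each cluster's *major peak-valley pair* — the
   largest-span peak→valley excursion crossing zero — marks an abrupt
   foot-ground force change. The push-off/swing boundary fuses the sagittal
   peak and vertical valley; the swing/heel-strike boundary fuses the two
   peaks. The four-reference variant adds the nearest derivative
   zero-crossings and rejects outliers by a leave-one-out 3-SD rule before
   averaging.

3. **Per-phase stride-length regression with mean fusion.** For each
   dynamic phase, 12 features (Weinberg term `(a_max−a_min)^{1/4}`, Kim
   term `(Σ|a_i|/N)^{1/3}`, variance, range — each on the sagittal,
   vertical and magnitude channels) are standardized to zero mean / unit
   SD, filtered by random-forest importance, and fed to an SVR with RBF
   kernel (optionally AdaBoost.R2-boosted). The stride estimate is the mean
   of the three per-phase predictions, which transfers across walking
   speeds better than a single whole-stride model.

Evaluation utilities implement segment-level precision/recall/F-score with
greedy one-to-one matching, temporal IoU (union defined as the spanning
interval), RMSE and relative distance error. A seeded synthetic gait-signal
generator produces walks with ground-truth stride intervals, phase
boundaries and stride lengths at configurable cadence and noise, so the
whole pipeline is testable without any sensor hardware.

All sample indices in the public API are **0-based**, and all intervals are
**half-open** `[start, end)`, so phases tile a stride exactly and IoU
arithmetic is exact.

## Worked example

```r
library(gaitstride)

walk <- generate_walk(walk_config(n_strides = 30, cadence_hz = 0.9,
                                  noise_sd = 0.05, seed = 42))
walk
#> <synthetic_walk: 30 strides, 3330 samples @ 100 Hz, noise 0.05>

seg <- segment_gait(walk$recording, walk$truth$strides, mode = "four_ref")
seg
#> <gait_segmentation (four_ref): 30 strides segmented, 0 failed>
evaluate_phases(seg$phases, walk$truth$phases)
#>         phase tp fp fn precision recall f_score  mean_iou
#> 1      stance 30  0  0         1      1       1 0.8451108
#> 2    push_off 30  0  0         1      1       1 1.0000000
#> 3       swing 30  0  0         1      1       1 1.0000000
#> 4 heel_strike 30  0  0         1      1       1 0.8154904
```

Every stride was found and divided into its four phases (F-score 1); the
mean temporal IoU says how tightly each predicted phase hugs the true one —
the dynamic-boundary phases are exact here, while the stance/heel-strike
split wanders by a few samples under noise.

```r
fd <- build_feature_dataset(walk$recording, walk$truth$strides,
                            walk$truth$phases, cadence_hz = 0.9)
model <- train_stride_model(fd, walk$truth$stride_lengths,
                            model_type = "svr_rbf", seed = 1)

test <- generate_walk(walk_config(n_strides = 10, cadence_hz = 0.9,
                                  noise_sd = 0.05, seed = 43))
fd_test <- build_feature_dataset(test$recording, test$truth$strides,
                                 test$truth$phases, cadence_hz = 0.9)
pred <- predict(model, fd_test)
round(pred$estimate, 3)
#>  [1] 1.521 1.520 1.529 1.540 1.530 1.532 1.538 1.535 1.534 1.542
rmse(test$truth$stride_lengths, pred$estimate)
#> [1] 0.03629969
relative_error(sum(test$truth$stride_lengths), pred$estimate)
#> [1] -0.1947964
```

The fused model estimates each stride of an unseen walk to within about
3.6 cm RMSE (the generator's length noise is 3 cm), and the accumulated
distance is off by 0.19 % — the estimator slightly overshoots the true
path length here, hence the negative sign.

`run_pipeline(recording, template, model)` chains stride detection, phase
division, feature extraction and length fusion; `inst/cli/gaitstride.R` is a
thin command-line wrapper with subcommands `simulate`, `template`,
`strides`, `gait`, `train`, `predict`, `evaluate`, all file-in/file-out.

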