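# Shared fixture builders (all data generated in code).

# minimal recording with prescribed sagittal/vertical acceleration and
# quiet remaining channels
make_rec <- function(sag, vert, fs = 100) {
  n <- length(sag)
  stopifnot(length(vert) == n)
  accel <- cbind(acc_x = rep(0, n), acc_y = sag, acc_z = vert)
  gyro <- cbind(gyr_x = rep(0, n), gyr_y = rep(0, n), gyr_z = rep(0, n))
  imu_recording((seq_len(n) - 1) / fs, accel, gyro,
                channel_map = list(
                  accel = c(coronal = "acc_x", sagittal = "acc_y",
                            vertical = "acc_z"),
                  gyro = c(coronal = "gyr_x", sagittal = "gyr_y",
                           vertical = "gyr_z")),
                sample_rate_hz = fs)
}

# segment a synthetic walk quietly (fallback warnings are part of normal
# noisy operation)
segment_quiet <- function(rec, strides, mode, cfg = gait_config()) {
  suppressWarnings(segment_gait(rec, strides, mode, cfg))
}

# gyroscope coronal template from a walk's true strides (excluding a
# terminal half-stride if present)
walk_template <- function(walk) {
  gyr <- channel(walk$recording, "coronal", "gyro")
  strides <- walk$truth$strides
  if (walk$config$include_half_stride) strides <- head(strides, -1)
  build_template(lapply(seq_len(nrow(strides)), function(k)
    gyr[(strides$start[k] + 1):strides$end[k]]))
}

# mean absolute fused-boundary error against the planted events
boundary_mae <- function(walk, seg) {
  ev <- walk$injected_events
  idx <- match(seg$boundaries$stride_start, walk$truth$strides$start)
  mean(c(abs(seg$boundaries$push_off_swing - ev$b1[idx]),
         abs(seg$boundaries$swing_heel_strike - ev$b2[idx])))
}
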