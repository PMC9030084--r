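test_that("generation is bitwise deterministic given the seed", {
  cfg <- walk_config(n_strides = 6, cadence_hz = 0.9, noise_sd = 0.08,
                     include_half_stride = TRUE, seed = 12)
  w1 <- generate_walk(cfg)
  w2 <- generate_walk(cfg)
  expect_identical(w1$recording$accel, w2$recording$accel)
  expect_identical(w1$recording$gyro, w2$recording$gyro)
  expect_identical(w1$truth$stride_lengths, w2$truth$stride_lengths)
  w3 <- generate_walk(walk_config(n_strides = 6, cadence_hz = 0.9,
                                  noise_sd = 0.08,
                                  include_half_stride = TRUE, seed = 13))
  expect_false(identical(w1$recording$accel, w3$recording$accel))
})

test_that("ground-truth phases tile each full stride", {
  w <- generate_walk(walk_config(n_strides = 8, cadence_hz = 0.8,
                                 include_half_stride = TRUE, seed = 2))
  strides <- w$truth$strides
  full <- head(strides, -1)
  for (k in seq_len(nrow(full))) {
    ph <- w$truth$phases[w$truth$phases$start >= full$start[k] &
                           w$truth$phases$end <= full$end[k], ]
    expect_equal(nrow(ph), 4L)
    expect_equal(sum(ph$end - ph$start), full$end[k] - full$start[k])
  }
  # half-stride: moving half followed by quiescence, no phase labels
  half <- tail(strides, 1)
  expect_false(any(w$truth$phases$start >= half$start))
  expect_lt(half$end - half$start, min(full$end - full$start))
})

test_that("planted peak-valley pairs sit on the phase boundaries", {
  w <- generate_walk(walk_config(n_strides = 5, cadence_hz = 1.0, seed = 6))
  ev <- w$injected_events
  truth_ph <- w$truth$phases
  b1 <- truth_ph$start[truth_ph$phase == "swing"]
  b2 <- truth_ph$start[truth_ph$phase == "heel_strike"]
  expect_equal(ev$sag_peak_left, b1)
  expect_equal(ev$vert_valley_left, b1)
  expect_equal(ev$sag_peak_right, b2)
  expect_equal(ev$vert_peak_right, b2)

  # the planted indices are actual extrema of the noise-free channels
  sag <- channel(w$recording, "sagittal")
  vert <- channel(w$recording, "vertical")
  for (k in seq_len(nrow(ev))) {
    iv <- w$truth$strides[k, ]
    seg_s <- sag[(iv$start + 1):iv$end]
    seg_v <- vert[(iv$start + 1):iv$end]
    expect_equal(iv$start + which.max(seg_s) - 1L, ev$sag_peak_left[k])
    expect_equal(iv$start + which.min(seg_v) - 1L, ev$vert_valley_left[k])
  }
})

test_that("faster cadence produces larger vertical excursions", {
  rng <- function(cad) {
    w <- generate_walk(walk_config(n_strides = 1, cadence_hz = cad,
                                   seed = 1))
    diff(range(channel(w$recording, "vertical")))
  }
  spans <- vapply(c(0.6, 0.8, 1.0, 1.2), rng, numeric(1))
  expect_true(all(diff(spans) > 0))
})

test_that("noise-free stance is recovered with IoU >= 0.95", {
  for (cad in c(0.7, 0.9, 1.1)) {
    w <- generate_walk(walk_config(n_strides = 10, cadence_hz = cad,
                                   seed = 14))
    truth_st <- w$truth$phases[w$truth$phases$phase == "stance", ]
    for (k in seq_len(10)) {
      iv <- sample_interval(w$truth$strides$start[k],
                            w$truth$strides$end[k])
      st <- detect_stance(w$recording, iv)
      expect_gte(interval_iou(st$interval,
                              sample_interval(truth_st$start[k],
                                              truth_st$end[k])), 0.95)
    }
  }
})

test_that("dataset grids enumerate cadence x seed with a manifest", {
  ds <- generate_dataset(c(0.7, 0.9, 1.1), seeds = c(1, 2), n_strides = 3)
  expect_length(ds$walks, 6L)
  expect_equal(nrow(ds$manifest), 6L)
  expect_setequal(ds$manifest$cadence, c(0.7, 0.9, 1.1))
  expect_error(generate_dataset(numeric(0), 1, n_strides = 3), "non-empty")
  # regeneration from the manifest is identical
  i <- 4
  again <- generate_walk(walk_config(n_strides = 3,
                                     cadence_hz = ds$manifest$cadence[i],
                                     seed = ds$manifest$seed[i]))
  expect_identical(again$recording$accel, ds$walks[[i]]$recording$accel)
})
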