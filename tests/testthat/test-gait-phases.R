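test_that("preprocessing is a moving mean followed by signed squaring", {
  expect_equal(preprocess(rep(3, 10), 5), rep(9, 10))
  expect_equal(preprocess(rep(-3, 10), 5), rep(-9, 10))
  expect_equal(preprocess(-2, 1), -4)
  expect_equal(preprocess(rep(0, 7), 3), rep(0, 7))
  expect_error(preprocess(1:10, 4), "odd")
})

test_that("stance is the quiet terminal segment of a stride", {
  n <- 100
  active <- 10 * sin(2 * pi * (1:70) / 7)
  sag <- c(active, rep(0, 30))
  vert <- c(active, rep(0, 30))
  rec <- make_rec(sag, vert)
  st <- detect_stance(rec, sample_interval(0, n))
  expect_s3_class(st, "stance_phase")
  expect_lte(abs(st$interval$start - 70), 5)
  expect_equal(st$interval$end, 100)

  # fast high-amplitude oscillation everywhere: volatile at every window
  osc <- 10 * rep(c(1, -1, 0.5, -0.5), 25)
  expect_null(detect_stance(make_rec(osc, osc), sample_interval(0, n)))

  # generator stride at moderate noise recovers the true stance region
  w <- generate_walk(walk_config(n_strides = 6, cadence_hz = 0.9,
                                 noise_sd = 0.05, seed = 4))
  iv <- sample_interval(w$truth$strides$start[3], w$truth$strides$end[3])
  st2 <- detect_stance(w$recording, iv)
  truth <- w$truth$phases[w$truth$phases$phase == "stance", ][3, ]
  expect_gte(interval_iou(st2$interval,
                          sample_interval(truth$start, truth$end)), 0.8)
})

test_that("extrema detection finds prominent strict extrema, plateaus once", {
  tri <- c(0, 1, 2, 3, 2, 1, 0)
  ex <- find_extrema(tri, min_prominence = 0.5)
  expect_equal(ex$peaks, 3L)
  expect_length(ex$valleys, 0L)

  ex2 <- find_extrema(as.numeric(1:20), min_prominence = 0)
  expect_length(ex2$peaks, 0L)
  expect_length(ex2$valleys, 0L)

  plateau <- c(0, 2, 2, 0, 0)
  ex3 <- find_extrema(plateau, min_prominence = 0.5)
  expect_equal(ex3$peaks, 1L)  # first index of the two equal maxima

  # prominence floor: small ripple on a big peak is rejected
  x <- c(0, 10, 0.2, 0.5, 0.2, 10, 0)
  ex4 <- find_extrema(x, min_prominence = 1)
  expect_equal(ex4$peaks, c(1L, 5L))
})

test_that("extrema clustering matches the exhaustive WCSS bipartition", {
  cl <- cluster_extrema(c(10, 12, 14, 50, 52), 8, 55)
  expect_equal(cl$left, c(10L, 12L, 14L))
  expect_equal(cl$right, c(50L, 52L))

  one <- cluster_extrema(3, 0, 10)
  expect_equal(one$left, 3L)
  expect_length(one$right, 0L)

  tie <- cluster_extrema(5, 0, 10)   # equidistant -> left
  expect_equal(tie$left, 5L)

  expect_length(cluster_extrema(integer(0), 0, 10)$left, 0L)

  for (seed in 1:50) {
    set.seed(seed)
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    c1 <- sample(5:20, 1)
    diam <- sample(1:6, 1)
    offs <- function(n) sample.int(diam + 1L, n, replace = TRUE) - 1L
    left <- sort(c1 + offs(n1))
    gap <- max(diam, 1) * 3 + sample(5:15, 1)
    right <- sort(max(left) + gap + offs(n2))
    pts <- c(left, right)
    cl <- cluster_extrema(pts, min(pts) - 2, max(pts) + 2)
    oracle <- wcss_bipartition(pts)
    expect_equal(sort(cl$left), oracle$left)
    expect_equal(sort(cl$right), oracle$right)
  }
})

test_that("major peak-valley pairs require a zero crossing and merge", {
  x <- rep(0, 30)
  x[10:15 + 1] <- c(2, 1, 0.2, -0.4, -1.2, -2)   # 0-based 10..15
  x[15:19 + 1] <- c(-2, -1, 0, 0.5, 0)
  pvp <- find_major_pvp(x, peaks = 10, valleys = 15)
  expect_equal(pvp$peak_index, 10L)
  expect_equal(pvp$valley_index, 15L)
  expect_equal(pvp$span, 4)

  # secondary pair with span > half the major span and peak within 5
  # samples of the major valley merges into (first peak, second valley)
  y <- rep(0, 30)
  y[10 + 1] <- 2; y[12 + 1] <- 0; y[14 + 1] <- -2
  y[17 + 1] <- 1.3; y[19 + 1] <- 0; y[21 + 1] <- -1.1
  pvp2 <- find_major_pvp(y, peaks = c(10, 17), valleys = c(14, 21))
  expect_equal(pvp2$peak_index, 10L)
  expect_equal(pvp2$valley_index, 21L)
  expect_equal(pvp2$span, y[11] - y[22])

  z <- abs(sin(seq(0, 4 * pi, length.out = 50))) + 1
  ex <- find_extrema(z, min_prominence = 0.1)
  expect_null(find_major_pvp(z, ex$peaks, ex$valleys))
})

test_that("derivative zero crossings reference the pair extrema", {
  x <- sin(2 * pi * (0:99) / 50)
  d <- x[c(2:100, 100)] - x   # first difference, trailing replication
  pvp <- structure(list(peak_index = 12L, valley_index = 37L),
                   class = "peak_valley_pair")
  neg <- zero_crossing_refs(d, pvp, "negative")
  expect_lte(abs(neg - 12), 1)
  pos <- zero_crossing_refs(d, pvp, "positive")
  expect_lte(abs(pos - 37), 1)
  expect_null(zero_crossing_refs(rep(1, 50), pvp, "negative"))
})

test_that("leave-one-out outlier rejection drops only far references", {
  expect_equal(reject_outliers(c(100, 100, 100, 100)), c(100, 100, 100, 100))
  # leave-one-out fit on {100,101,102}: mean 101, sd 1; 300 is > 3 sd out
  expect_equal(reject_outliers(c(100, 101, 102, 300)), c(100, 101, 102))
  expect_equal(reject_outliers(c(100, 200)), c(100, 200))  # < 4 refs: skip
})

test_that("boundary fusion averages the references of the chosen mode", {
  w <- generate_walk(walk_config(n_strides = 4, cadence_hz = 0.9, seed = 9))
  iv <- sample_interval(w$truth$strides$start[2], w$truth$strides$end[2])
  ev <- w$injected_events[2, ]
  for (mode in c("two_ref", "four_ref")) {
    lb <- locate_boundaries(w$recording, iv, mode)
    n_refs <- if (mode == "two_ref") 2L else 4L
    expect_equal(nrow(lb$push_off_swing$references), n_refs)
    fused <- lb$push_off_swing$fused_index
    refs <- lb$push_off_swing$references$index
    if (mode == "two_ref") {
      # fused index is the round-half-away-from-zero mean of the references
      expect_equal(fused, as.integer(sign(mean(refs)) *
                                       floor(abs(mean(refs)) + 0.5)))
    } else {
      expect_gte(fused, min(refs))
      expect_lte(fused, max(refs))
    }
    expect_lte(abs(fused - ev$b1), 2)
    expect_lte(abs(lb$swing_heel_strike$fused_index - ev$b2), 2)
    expect_true(iv$start < lb$push_off_swing$fused_index)
    expect_true(lb$swing_heel_strike$fused_index < lb$stance$interval$start)
  }
})

test_that("gait segmentation tiles every successful stride exactly", {
  w <- generate_walk(walk_config(n_strides = 12, cadence_hz = 0.9,
                                 noise_sd = 0.05, seed = 21))
  seg <- segment_quiet(w$recording, w$truth$strides, "four_ref")
  for (k in seq_len(nrow(seg$boundaries))) {
    b <- seg$boundaries[k, ]
    ph <- seg$phases[seg$phases$start >= b$stride_start &
                       seg$phases$end <= b$stride_end, ]
    expect_equal(nrow(ph), 4L)
    expect_equal(sum(ph$end - ph$start), b$stride_end - b$stride_start)
    ord <- ph[match(c("push_off", "swing", "heel_strike", "stance"),
                    ph$phase), ]
    expect_equal(ord$start[-1], ord$end[-4])  # contiguous in phase order
  }
})

test_that("strides without boundaries are reported, not dropped silently", {
  flat <- make_rec(rep(0, 200), rep(0, 200))
  seg <- segment_quiet(flat, data.frame(start = 0L, end = 200L), "four_ref")
  expect_equal(nrow(seg$phases), 0L)
  expect_equal(nrow(seg$diagnostics), 1L)
})

test_that("a 50-stride noisy walk yields four phases for every stride", {
  w <- generate_walk(walk_config(n_strides = 50, cadence_hz = 0.9,
                                 noise_sd = 0.1, seed = 1))
  seg <- segment_quiet(w$recording, w$truth$strides, "four_ref")
  expect_equal(nrow(seg$boundaries), 50L)
  expect_equal(nrow(seg$phases), 200L)
  expect_equal(nrow(seg$diagnostics), 0L)
})

test_that("boundary error shrinks with noise and four_ref never trails
           two_ref on noise-free walks", {
  maes <- vapply(c(0.1, 0.05, 0), function(ns) {
    w <- generate_walk(walk_config(n_strides = 20, cadence_hz = 0.9,
                                   noise_sd = ns, seed = 8))
    boundary_mae(w, segment_quiet(w$recording, w$truth$strides, "four_ref"))
  }, numeric(1))
  expect_true(all(diff(maes) <= 1e-12))
  expect_lte(maes[3], 2)

  for (cad in c(0.7, 0.9, 1.1)) {
    w <- generate_walk(walk_config(n_strides = 15, cadence_hz = cad,
                                   seed = 8))
    m4 <- boundary_mae(w, segment_quiet(w$recording, w$truth$strides,
                                        "four_ref"))
    m2 <- boundary_mae(w, segment_quiet(w$recording, w$truth$strides,
                                        "two_ref"))
    expect_lte(m4, m2)
  }
})
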