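test_that("templates average length-normalized strides", {
  s <- sin(seq(0, 2 * pi, length.out = 40))
  tpl <- build_template(list(s, s), L = 40)
  expect_equal(tpl$values, s)

  tpl2 <- build_template(list(rep(1, 17), rep(3, 52)), L = 10)
  expect_equal(tpl2$values, rep(2, 10))

  # frozen from an independent linear-interpolation oracle: [0,2,4,6]
  # resampled to 4 points stays [0,2,4,6]; column means with [0,1,2,3]
  tpl3 <- build_template(list(c(0, 1, 2, 3), c(0, 2, 4, 6)), L = 4)
  expect_equal(tpl3$values, c(0, 1.5, 3, 4.5))

  expect_error(build_template(list()), "at least one")

  path <- withr::local_tempfile(fileext = ".json")
  write_template(tpl, path)
  back <- read_template(path)
  expect_equal(back$values, tpl$values)
  expect_equal(back$L, tpl$L)
})

test_that("neighborhood descriptors evaluate the documented formulas", {
  cfg <- sdatw_config(w = 2)
  expect_equal(neighborhood_features(rep(5, 20), 10, cfg), c(0, 0, 5))
  # unit-slope signal: mean gradient 1, amplitude range 2w, mean = value
  x <- as.numeric(0:19)
  expect_equal(neighborhood_features(x, 10, cfg), c(1, 4, 10))
  # replication padding at the sequence start
  padded <- c(x[1], x[1], x)
  manual <- c(mean(diff(padded[1:5])), diff(range(padded[1:5])),
              mean(padded[1:5]))
  expect_equal(neighborhood_features(x, 0, cfg), manual)
})

test_that("a stream equal to the template yields one exact self-match", {
  tpl_vals <- sin(2 * pi * seq(0, 1, length.out = 60)) +
    seq(0, 1, length.out = 60)
  tpl <- build_template(list(tpl_vals), L = 60)
  m <- sdatw_match(tpl_vals, tpl)
  expect_equal(nrow(m$matches), 1L)
  expect_equal(m$matches$start, 0L)
  expect_equal(m$matches$end, 60L)
  expect_lt(m$matches$accumulated_distance, 1e-6)
  expect_error(sdatw_match(tpl_vals[1:20], tpl), "shorter")
})

test_that("time-stretched copies are segmented at the concatenation joints", {
  u <- seq(0, 1, length.out = 60)
  tpl_vals <- sin(2 * pi * u) + 0.5 * sin(4 * pi * u) + u
  tpl <- build_template(list(tpl_vals), L = 60)
  stretched <- stats::approx(seq_along(tpl_vals), tpl_vals, n = 90)$y
  stream <- c(tpl_vals, stretched, tpl_vals)
  m <- sdatw_match(stream, tpl)
  expect_equal(nrow(m$matches), 3L)
  joints <- c(0, 60, 150, 210)
  expect_true(all(abs(m$matches$start - joints[1:3]) <= 3))
  expect_true(all(abs(m$matches$end - joints[2:4]) <= 3))
})

test_that("a terminal half-stride followed by quiescence is still matched", {
  u <- seq(0, 1, length.out = 60)
  tpl_vals <- sin(2 * pi * u) + 0.5 * sin(4 * pi * u) + u
  tpl <- build_template(list(tpl_vals), L = 60)
  stream <- c(tpl_vals, tpl_vals, tpl_vals[1:30], rep(0, 40))
  m <- sdatw_match(stream, tpl)
  expect_equal(nrow(m$matches), 3L)
  # the last match covers the half copy at samples 120..149
  last <- m$matches[3, ]
  expect_lte(last$start, 122)
  expect_gte(last$end, 148)
})

test_that("best-match distance equals the brute-force subsequence DTW", {
  cfg <- sdatw_config(w = 3, min_match_frac = 0)
  for (seed in 1:3) {
    set.seed(seed)
    L <- sample(16:24, 1)
    n <- sample(120:160, 1)
    tpl_vals <- cumsum(rnorm(L))
    stream <- cumsum(rnorm(n))
    tpl <- build_template(list(tpl_vals), L = L)
    cost <- gaitstride:::sdatw_cost(
      neighborhood_features(stream, NULL, cfg),
      neighborhood_features(tpl$values, NULL, cfg))
    m <- sdatw_match(stream, tpl, cfg)
    expect_equal(min(m$matches$accumulated_distance),
                 brute_force_subdtw_min(cost), tolerance = 1e-9)
  }
})

test_that("matches are ordered, non-overlapping, with monotone paths", {
  for (seed in 1:5) {
    set.seed(seed)
    tpl_vals <- cumsum(rnorm(30))
    stream <- cumsum(rnorm(300))
    tpl <- build_template(list(tpl_vals), L = 30)
    m <- sdatw_match(stream, tpl, sdatw_config(w = 3))
    mm <- m$matches
    if (nrow(mm) > 1) {
      expect_true(all(diff(mm$start) > 0))
      expect_true(all(mm$start[-1] >= mm$end[-nrow(mm)]))
    }
    for (p in m$paths) {
      expect_true(all(diff(p[, 1]) >= 0))
      expect_true(all(diff(p[, 2]) >= 0))
    }
    expect_true(all(mm$accumulated_distance >= 0))
  }
})

test_that("normalized descriptors make boundaries amplitude-invariant", {
  w <- generate_walk(walk_config(n_strides = 8, cadence_hz = 0.9,
                                 noise_sd = 0.03, seed = 5))
  gyr <- channel(w$recording, "coronal", "gyro")
  tpl <- walk_template(w)
  cfg <- sdatw_config(normalize = TRUE)
  base <- sdatw_match(gyr, tpl, cfg)$matches
  for (scale in c(0.2, 5)) {
    scaled <- sdatw_match(scale * gyr, tpl, cfg)$matches
    expect_equal(scaled$start, base$start)
    expect_equal(scaled$end, base$end)
  }
})
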