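test_that("feature terms evaluate the empirical step-length formulas", {
  n <- 50
  rec8 <- make_rec(rep(0, n), rep(8, n))
  f <- compute_features(rec8, cadence_hz = 1)
  expect_equal(unname(f["vertical_kim"]), 2)        # (mean |8|)^(1/3)
  expect_equal(unname(f["vertical_weinberg"]), 0)   # flat channel
  expect_equal(unname(f["vertical_variance"]), 0)

  alt <- make_rec(rep(c(1, -1), n / 2), rep(0, n))
  f2 <- compute_features(alt, cadence_hz = 1)
  expect_equal(unname(f2["sagittal_weinberg"]), 2^(1 / 4))
  expect_equal(unname(f2["sagittal_kim"]), 1)
  expect_equal(unname(f2["sagittal_range"]), 2)

  cfg <- model_config(include_cadence = TRUE, include_scarlett = TRUE)
  f3 <- compute_features(rec8, cadence_hz = 0.9, cfg)
  expect_equal(unname(f3["cadence"]), 0.9)
  expect_equal(unname(f3["scarlett"]), 0)  # flat magnitude: fallback, no error
  expect_length(compute_features(rec8, 1), 12L)

  expect_error(compute_features(slice_recording(rec8, sample_interval(0, 1)),
                                1), "at least 2")
  expect_error(compute_features(rec8, 0), "positive")
})

test_that("standardization yields unit-SD zero-mean columns, drops constants", {
  got <- standardize(cbind(a = c(1, 2, 3)))
  expect_equal(unname(got$X_norm[, 1]), c(-1, 0, 1))
  expect_equal(unname(got$scaler$mean), 2)
  expect_equal(unname(got$scaler$sd), 1)

  set.seed(3)
  X <- cbind(a = rnorm(40, 5, 2), b = runif(40), c = rep(7, 40))
  std <- standardize(X)
  expect_equal(std$scaler$dropped, "c")
  expect_true(all(abs(colMeans(std$X_norm)) < 1e-9))
  expect_true(all(abs(apply(std$X_norm, 2, sd) - 1) < 1e-9))
  # idempotence: standardizing an already-standardized matrix changes nothing
  again <- standardize(std$X_norm)
  expect_equal(again$X_norm, std$X_norm, tolerance = 1e-9)
  # stored parameters reproduce the transform on new data
  expect_equal(apply_scaler(std$scaler, X), std$X_norm)
})

test_that("random-forest importances select the generating feature", {
  set.seed(10)
  X <- matrix(rnorm(500 * 6), 500, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, 3]
  sel <- select_features(X, y, threshold = 0.05, seed = 99)
  expect_equal(sel$importance$feature[1], "f3")
  expect_true("f3" %in% sel$selected)
  expect_equal(sum(sel$importance$importance), 1, tolerance = 1e-9)

  all_sel <- select_features(X, y, threshold = 0, seed = 99)
  expect_setequal(all_sel$selected,
                  colnames(X)[all_sel$importance$importance > 0])

  sel2 <- select_features(X, y, threshold = 0.05, seed = 99)
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$importance, sel2$importance)
})

test_that("training validates inputs and is seed-deterministic", {
  w <- generate_walk(walk_config(n_strides = 40, cadence_hz = 0.9,
                                 speed_profile = "ramp",
                                 cadence_range = c(0.75, 1.05),
                                 noise_sd = 0.05, seed = 31))
  fd <- build_feature_dataset(w$recording, w$truth$strides, w$truth$phases,
                              w$config$cadence_hz)
  lens <- w$truth$stride_lengths
  expect_error(train_stride_model(fd, lens, "nonsense"))
  expect_error(
    train_stride_model(lapply(fd[c("push_off", "swing", "heel_strike")],
                              function(M) M[1:5, , drop = FALSE]),
                       lens[1:5]),
    "insufficient")

  m1 <- train_stride_model(fd, lens, "svr_rbf", seed = 7)
  m2 <- train_stride_model(fd, lens, "svr_rbf", seed = 7)
  expect_identical(lapply(m1$phases, `[[`, "selected"),
                   lapply(m2$phases, `[[`, "selected"))
  p1 <- predict(m1, fd)$estimate
  p2 <- predict(m2, fd)$estimate
  expect_identical(p1, p2)
})

test_that("prediction fuses per-phase estimates by their mean", {
  w <- generate_walk(walk_config(n_strides = 40, cadence_hz = 0.9,
                                 speed_profile = "ramp",
                                 cadence_range = c(0.75, 1.05),
                                 noise_sd = 0.05, seed = 31))
  fd <- build_feature_dataset(w$recording, w$truth$strides, w$truth$phases,
                              w$config$cadence_hz)
  model <- train_stride_model(fd, w$truth$stride_lengths, "svr_rbf",
                              seed = 7)
  pred <- predict(model, fd)
  per_phase <- sapply(c("push_off", "swing", "heel_strike"), function(ph)
    gaitstride:::predict_one_regressor(model$phases[[ph]], fd[[ph]]))
  expect_equal(pred$estimate, rowMeans(per_phase))
  expect_false(any(pred$partial))

  # a missing phase triggers partial fusion over the remaining ones
  fd_part <- fd
  fd_part$push_off[3, ] <- NA_real_
  pred2 <- predict(model, fd_part)
  expect_true(pred2$partial[3])
  expect_equal(pred2$n_phases[3], 2)
  expect_equal(pred2$estimate[3], mean(per_phase[3, c("swing",
                                                      "heel_strike")]))
  expect_equal(pred2$estimate[-3], pred$estimate[-3])
})

test_that("a planted affine length map is recovered within 1.5 noise SDs", {
  sigma <- 0.05
  lmap <- function(f) 3 * f[["vertical_weinberg"]]
  feats <- list(); lens <- c()
  cads <- seq(0.7, 1.1, length.out = 5)
  for (i in seq_along(cads)) {
    w <- generate_walk(walk_config(n_strides = 40, cadence_hz = cads[i],
                                   noise_sd = 0.05, seed = 300 + i,
                                   length_map = lmap,
                                   length_noise_sd = sigma))
    feats[[i]] <- build_feature_dataset(w$recording, w$truth$strides,
                                        w$truth$phases, cads[i])
    lens <- c(lens, w$truth$stride_lengths)
  }
  X <- lapply(c(push_off = "push_off", swing = "swing",
                heel_strike = "heel_strike", whole_stride = "whole_stride"),
              function(nm) do.call(rbind, lapply(feats, `[[`, nm)))
  set.seed(77)
  test_idx <- sample(length(lens), 50)
  model <- train_stride_model(lapply(X, function(M) M[-test_idx, ]),
                              lens[-test_idx], "svr_rbf", seed = 5)
  est <- predict(model, lapply(X, function(M) M[test_idx, ]))$estimate
  expect_lte(rmse(lens[test_idx], est), 1.5 * sigma)
})
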