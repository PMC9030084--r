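# Per-gait-phase feature extraction, standardization, importance-based
# feature selection, per-phase regression (SVR-RBF, optionally AdaBoost.R2
# boosted), and mean fusion into a stride-length estimate.
#
# The features are the terms of the classical empirical step-length models:
# Weinberg's quartic-root acceleration span, Kim's cube-root mean absolute
# acceleration, Ladetto's frequency and variance terms, and Scarlett's
# normalized mean. Their multiplicative constants are absorbed by the
# downstream regressor rather than fixed here.

#' Model configuration for stride-length estimation
#'
#' @param registry which per-channel feature terms to compute; the default
#'   four terms over three channels yield the 12-feature set.
#' @param include_cadence,include_scarlett optional extra features (cadence
#'   in strides/s; Scarlett's normalized mean on the magnitude channel).
#' @param importance_threshold random-forest importance share above which a
#'   feature is selected.
#' @param rf_ntree trees used for the importance measurement.
#' @param svr_cost,svr_epsilon,svr_gamma SVR-RBF hyperparameters; `NULL`
#'   gamma means `1/n_features` after selection.
#' @param adaboost_n,adaboost_loss AdaBoost.R2 ensemble size and loss
#'   (`"linear"`, `"square"` or `"exponential"`).
#' @param min_train_strides minimum strides (all three phases present)
#'   required for training.
#' @return A list of class `model_config`.
#' @export
model_config <- function(registry = c("weinberg", "kim", "variance", "range"),
                         include_cadence = FALSE, include_scarlett = FALSE,
                         importance_threshold = 0.05, rf_ntree = 300L,
                         svr_cost = 10, svr_epsilon = 0.01, svr_gamma = NULL,
                         adaboost_n = 30L,
                         adaboost_loss = c("linear", "square", "exponential"),
                         min_train_strides = 20L) {
  adaboost_loss <- match.arg(adaboost_loss)
  registry <- match.arg(registry, c("weinberg", "kim", "variance", "range"),
                        several.ok = TRUE)
  structure(list(registry = registry,
                 include_cadence = isTRUE(include_cadence),
                 include_scarlett = isTRUE(include_scarlett),
                 importance_threshold = importance_threshold,
                 rf_ntree = as.integer(rf_ntree),
                 svr_cost = svr_cost, svr_epsilon = svr_epsilon,
                 svr_gamma = svr_gamma,
                 adaboost_n = as.integer(adaboost_n),
                 adaboost_loss = adaboost_loss,
                 min_train_strides = as.integer(min_train_strides)),
            class = "model_config")
}

# the four per-channel feature terms; flat signals fall back to 0 where a
# term would otherwise be 0/0
channel_feature_set <- function(x, prefix,
                                registry = c("weinberg", "kim", "variance",
                                             "range")) {
  rng <- max(x) - min(x)
  vals <- c(weinberg = rng^(1 / 4),
            kim = mean(abs(x))^(1 / 3),
            variance = stats::var(x),
            range = rng)[registry]
  names(vals) <- paste(prefix, registry, sep = "_")
  vals
}

#' Compute stride-length features on a segment
#'
#' For each of the sagittal channel, the vertical channel, and the
#' per-sample Euclidean norm of the 3-axis acceleration ("magnitude"), the
#' configured terms are computed: `weinberg = (a_max - a_min)^(1/4)`,
#' `kim = (mean |a_i|)^(1/3)`, the variance, and the signal range. The
#' default 3 x 4 registry gives 12 features; cadence and Scarlett's
#' normalized mean `(1/N) sum (|a_i| - a_min) / (a_max - a_min)` (magnitude
#' channel) can be switched on. Flat channels yield 0 for the Weinberg and
#' Scarlett terms instead of an error.
#'
#' @param segment an `imu_recording` slice (length >= 2), e.g. one gait
#'   phase of one stride.
#' @param cadence_hz strides per second of the enclosing walk (> 0).
#' @param cfg a [model_config()].
#' @return Named numeric feature vector.
#' @export
compute_features <- function(segment, cadence_hz, cfg = model_config()) {
  if (n_samples(segment) < 2L)
    stop("segment must have at least 2 samples", call. = FALSE)
  if (!is.finite(cadence_hz) || cadence_hz <= 0)
    stop("cadence_hz must be positive", call. = FALSE)
  sag <- channel(segment, "sagittal")
  vert <- channel(segment, "vertical")
  mag <- sqrt(rowSums(segment$accel^2))
  feats <- c(channel_feature_set(sag, "sagittal", cfg$registry),
             channel_feature_set(vert, "vertical", cfg$registry),
             channel_feature_set(mag, "magnitude", cfg$registry))
  if (cfg$include_cadence) feats <- c(feats, cadence = cadence_hz)
  if (cfg$include_scarlett) {
    a <- abs(mag)
    rng <- max(a) - min(a)
    feats <- c(feats,
               scarlett = if (rng > 0) mean((a - min(a)) / rng) else 0)
  }
  if (any(!is.finite(feats)))
    stop("non-finite feature value", call. = FALSE)
  feats
}

#' Standardize a feature matrix to zero mean and unit SD
#'
#' Per column: subtract the mean and divide by the unbiased standard
#' deviation. Zero-variance columns cannot be standardized; they are dropped
#' and recorded in the returned scaler.
#'
#' @param X numeric matrix (strides x features) with column names.
#' @return List with `X_norm` (standardized matrix, zero-variance columns
#'   removed) and `scaler` (class `scaler_params`: per-feature `mean`, `sd`,
#'   plus `dropped` names), reusable via [apply_scaler()].
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  keep <- s > 0
  scaler <- structure(list(mean = mu[keep], sd = s[keep],
                           features = colnames(X)[keep],
                           dropped = colnames(X)[!keep]),
                      class = "scaler_params")
  list(X_norm = apply_scaler(scaler, X), scaler = scaler)
}

#' Apply stored standardization parameters to new data
#' @param scaler a `scaler_params` from [standardize()].
#' @param X feature matrix containing at least the scaler's features.
#' @return Standardized matrix restricted to the scaler's features.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)[, scaler$features, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Importance-based feature selection with a random forest
#'
#' Fits a seeded random-forest regressor and normalizes the impurity-based
#' importances to sum to one; features whose importance share exceeds the
#' threshold are selected. An empty selection falls back to the single
#' top-ranked feature.
#'
#' @param X feature matrix (strides x features).
#' @param y stride lengths.
#' @param threshold importance share cut-off.
#' @param seed integer seed (selection is deterministic given `X`, `y`,
#'   `seed`).
#' @param ntree forest size.
#' @return List with `selected` (character) and `importance` (data.frame
#'   `feature`, `importance`, descending).
#' @export
select_features <- function(X, y, threshold = 0.05, seed = 1L,
                            ntree = 300L) {
  X <- as.matrix(X)
  fit <- with_seed(seed,
    randomForest::randomForest(x = X, y = as.numeric(y), ntree = ntree))
  imp <- fit$importance[, "IncNodePurity"]
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  selected <- names(imp)[imp > threshold]
  if (!length(selected)) selected <- names(imp)[ord[1L]]
  list(selected = selected,
       importance = data.frame(feature = names(imp)[ord],
                               importance = unname(imp[ord]),
                               row.names = NULL))
}

# --- AdaBoost.R2 with SVR base learners -----------------------------------

fit_svr <- function(X, y, cfg) {
  gamma <- cfg$svr_gamma %||% (1 / ncol(X))
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = cfg$svr_cost, epsilon = cfg$svr_epsilon, gamma = gamma,
             scale = FALSE)
}

fit_adaboost_r2 <- function(X, y, cfg, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  models <- list(); betas <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(cfg$adaboost_n)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      fit <- fit_svr(X[idx, , drop = FALSE], y[idx], cfg)
      pred <- as.numeric(stats::predict(fit, X))
      err <- abs(pred - y)
      D <- max(err)
      if (D == 0) {
        models[[length(models) + 1L]] <- fit
        betas <- c(betas, 1e-10)
        break
      }
      L <- switch(cfg$adaboost_loss,
                  linear = err / D,
                  square = (err / D)^2,
                  exponential = 1 - exp(-err / D))
      eps <- sum(w * L)
      if (eps >= 0.5) {
        # degenerate round; keep one weakly-weighted model if none yet
        if (!length(models)) {
          models[[1L]] <- fit
          betas <- 0.999
        }
        break
      }
      beta <- eps / (1 - eps)
      models[[length(models) + 1L]] <- fit
      betas <- c(betas, beta)
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  })
  structure(list(models = models, betas = betas), class = "adaboost_r2")
}

# weighted-median combination of the base predictions
predict_adaboost_r2 <- function(object, X) {
  P <- vapply(object$models, function(m) as.numeric(stats::predict(m, X)),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  wts <- log(1 / object$betas)
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1L]]
  })
}

train_one_regressor <- function(X, y, cfg, model_type, seed) {
  sel <- select_features(X, y, cfg$importance_threshold, seed = seed,
                         ntree = cfg$rf_ntree)
  std <- standardize(X[, sel$selected, drop = FALSE])
  Xn <- std$X_norm
  fit <- if (model_type == "svr_rbf") fit_svr(Xn, y, cfg)
         else fit_adaboost_r2(Xn, y, cfg, seed)
  list(selected = sel$selected, importance = sel$importance,
       scaler = std$scaler, fit = fit, model_type = model_type)
}

predict_one_regressor <- function(reg, X) {
  Xn <- apply_scaler(reg$scaler, as.matrix(X))
  if (reg$model_type == "svr_rbf") as.numeric(stats::predict(reg$fit, Xn))
  else predict_adaboost_r2(reg$fit, Xn)
}

FUSION_PHASES <- c("push_off", "swing", "heel_strike")

#' Train per-phase stride-length regression models
#'
#' For each dynamic gait phase (push-off, swing, heel-strike): select
#' features by random-forest importance, standardize them, and fit the
#' regressor. A whole-stride model is trained the same way on full-stride
#' features for comparison. Prediction fuses the three per-phase estimates
#' by their arithmetic mean.
#'
#' @param phase_features named list with matrices `push_off`, `swing`,
#'   `heel_strike` and optionally `whole_stride` (rows = strides, aligned).
#' @param lengths numeric reference stride lengths, one per row.
#' @param model_type `"svr_rbf"` or `"svr_adaboost"`.
#' @param cfg a [model_config()].
#' @param seed integer seed controlling feature selection and boosting
#'   resampling; results are bitwise-reproducible given the seed.
#' @param length_unit unit metadata carried into predictions.
#' @return An object of class `stride_length_model`.
#' @export
train_stride_model <- function(phase_features, lengths,
                               model_type = c("svr_rbf", "svr_adaboost"),
                               cfg = model_config(), seed = 1L,
                               length_unit = "m") {
  model_type <- match.arg(model_type)
  missing_ph <- setdiff(FUSION_PHASES, names(phase_features))
  if (length(missing_ph))
    stop(sprintf("phase_features lacks: %s",
                 paste(missing_ph, collapse = ", ")), call. = FALSE)
  n <- length(lengths)
  if (n < cfg$min_train_strides)
    stop(sprintf("insufficient training data: %d strides < required %d",
                 n, cfg$min_train_strides), call. = FALSE)
  for (ph in intersect(names(phase_features),
                       c(FUSION_PHASES, "whole_stride")))
    if (nrow(phase_features[[ph]]) != n)
      stop(sprintf("%s features have %d rows but %d lengths given",
                   ph, nrow(phase_features[[ph]]), n), call. = FALSE)
  phases <- lapply(FUSION_PHASES, function(ph)
    train_one_regressor(as.matrix(phase_features[[ph]]), lengths, cfg,
                        model_type, seed))
  names(phases) <- FUSION_PHASES
  whole <- if (!is.null(phase_features$whole_stride))
    train_one_regressor(as.matrix(phase_features$whole_stride), lengths,
                        cfg, model_type, seed)
  structure(list(phases = phases, whole_stride = whole, fusion = "mean",
                 model_type = model_type, cfg = cfg, seed = seed,
                 length_unit = length_unit),
            class = "stride_length_model")
}

#' @export
print.stride_length_model <- function(x, ...) {
  cat(sprintf("<stride_length_model: %s, mean fusion over %s>\n",
              x$model_type, paste(FUSION_PHASES, collapse = " + ")))
  for (ph in FUSION_PHASES)
    cat(sprintf("  %-11s features: %s\n", ph,
                paste(x$phases[[ph]]$selected, collapse = ", ")))
  invisible(x)
}

#' Predict stride lengths by per-phase fusion
#'
#' Each phase model predicts from its phase's features; the stride estimate
#' is the arithmetic mean of the available per-phase predictions. Strides
#' with a missing phase (segmentation failure, encoded as an all-`NA`
#' feature row) are predicted from the remaining phases and flagged as
#' partial fusion.
#'
#' @param object a [train_stride_model()] result.
#' @param newdata named list of per-phase feature matrices (aligned rows;
#'   `NA` rows mark missing phases).
#' @param ... unused.
#' @return Data.frame with `estimate` (in the model's length unit),
#'   `n_phases` used, and logical `partial`.
#' @export
predict.stride_length_model <- function(object, newdata, ...) {
  n <- nrow(newdata[[FUSION_PHASES[1L]]])
  preds <- matrix(NA_real_, n, length(FUSION_PHASES),
                  dimnames = list(NULL, FUSION_PHASES))
  for (ph in FUSION_PHASES) {
    X <- as.matrix(newdata[[ph]])
    ok <- stats::complete.cases(X)
    if (any(ok))
      preds[ok, ph] <- predict_one_regressor(object$phases[[ph]],
                                             X[ok, , drop = FALSE])
  }
  n_phases <- rowSums(!is.na(preds))
  if (any(n_phases == 0))
    warning("strides with no usable phase produce NA estimates",
            call. = FALSE)
  data.frame(estimate = rowMeans(preds, na.rm = TRUE),
             n_phases = n_phases,
             partial = n_phases < length(FUSION_PHASES))
}

#' Predict stride lengths with the whole-stride comparison model
#' @param model a [train_stride_model()] result (trained with a
#'   `whole_stride` feature matrix).
#' @param X whole-stride feature matrix.
#' @return Numeric vector of estimates.
#' @export
predict_whole_stride <- function(model, X) {
  if (is.null(model$whole_stride))
    stop("model was trained without a whole-stride variant", call. = FALSE)
  predict_one_regressor(model$whole_stride, as.matrix(X))
}

#' Assemble per-phase feature matrices from a segmentation
#'
#' Rows are strides; strides lacking a phase get an `NA` row for it (and are
#' skipped by training, flagged by prediction).
#'
#' @param rec an `imu_recording`.
#' @param strides data.frame of stride intervals (`start`, `end`).
#' @param phases data.frame of phase labels (`phase`, `start`, `end`), e.g.
#'   the `phases` of [segment_gait()] or of a ground-truth
#'   [annotation_set()].
#' @param cadence_hz scalar or per-stride vector of stride rates.
#' @param cfg a [model_config()].
#' @return Named list of matrices `push_off`, `swing`, `heel_strike`,
#'   `whole_stride`, plus `complete` (logical: all three phases present).
#' @export
build_feature_dataset <- function(rec, strides, phases, cadence_hz,
                                  cfg = model_config()) {
  strides <- intervals_df(strides)
  ns <- nrow(strides)
  cadence_hz <- rep_len(cadence_hz, ns)
  out <- list()
  template_names <- NULL
  for (ph in FUSION_PHASES) {
    rows <- lapply(seq_len(ns), function(k) {
      sel <- phases$phase == ph & phases$start >= strides$start[k] &
        phases$end <= strides$end[k]
      if (!any(sel)) return(NULL)
      p <- phases[which(sel)[1L], ]
      if (p$end - p$start < 2L) return(NULL)
      compute_features(slice_recording(rec, sample_interval(p$start, p$end)),
                       cadence_hz[k], cfg)
    })
    found <- !vapply(rows, is.null, logical(1))
    if (is.null(template_names) && any(found))
      template_names <- names(rows[found][[1L]])
    M <- matrix(NA_real_, ns, length(template_names),
                dimnames = list(NULL, template_names))
    for (k in which(found)) M[k, ] <- rows[[k]]
    out[[ph]] <- M
  }
  whole <- t(vapply(seq_len(ns), function(k)
    compute_features(slice_recording(
      rec, sample_interval(strides$start[k], strides$end[k])),
      cadence_hz[k], cfg), numeric(length(template_names))))
  out$whole_stride <- whole
  out$complete <- Reduce(`&`, lapply(out[FUSION_PHASES],
                                     function(M) stats::complete.cases(M)))
  out
}
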