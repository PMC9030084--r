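# Seeded generator of foot-mounted IMU walking signals with ground-truth
# stride intervals, gait-phase boundaries and stride lengths.
#
# The per-stride waveform is a versioned set of piecewise raised-cosine
# kernels reproducing the morphology of walking acceleration at the foot:
# a push-off loading dip and terminal toe-off transient (major peak-valley
# pair with a zero crossing), a quiescent swing ending in a heel-impact
# transient, a heel-strike deceleration with a sub-peak, and a near-zero
# stance. Faster walking produces larger signal excursions, so the kernel
# amplitude grows linearly with cadence.

# --- versioned kernel constants (changing these invalidates frozen tests) --
KERNEL <- list(
  frac_push_off = 0.20, frac_swing = 0.35, frac_heel_strike = 0.15,
  frac_stance = 0.30,
  gravity = 9.80665,
  # amplitude maps, monotone in cadence (strides/s)
  accel_amp = function(cadence) 8 + 12 * cadence,      # m/s^2
  gyro_amp = function(cadence) 80 + 160 * cadence,     # deg/s
  pair_offset_frac = 0.05,   # peak-to-valley spacing of planted pairs
  bump_halfwidth_frac = 0.035,
  sub_peak_frac = 0.65       # heel-strike sub-peak position in the cycle
)

raised_cosine <- function(u, center, halfwidth, amp) {
  out <- numeric(length(u))
  inside <- abs(u - center) < halfwidth
  out[inside] <- amp * 0.5 * (1 + cos(pi * (u[inside] - center) / halfwidth))
  out
}

# smooth 0->1 ramp on [a, b]
ramp01 <- function(u, a, b) {
  out <- numeric(length(u))
  out[u >= b] <- 1
  mid <- u > a & u < b
  out[mid] <- 0.5 * (1 - cos(pi * (u[mid] - a) / (b - a)))
  out
}

# noise-free kernels for one stride of m samples at the given cadence.
# Returns channel matrix plus the planted event indices (0-based, relative
# to the stride start).
stride_kernel <- function(m, cadence) {
  K <- KERNEL
  A <- K$accel_amp(cadence)
  G <- K$gyro_amp(cadence)
  g <- K$gravity
  b1 <- round(K$frac_push_off * m)
  b2 <- round((K$frac_push_off + K$frac_swing) * m)
  st <- round((1 - K$frac_stance) * m)
  d <- max(5L, round(K$pair_offset_frac * m))
  h <- max(3L, round(K$bump_halfwidth_frac * m)) / m
  sub <- round(K$sub_peak_frac * m)
  u <- (seq_len(m) - 1L) / m

  sag <- raised_cosine(u, 0.10, 0.07, -0.5 * A) +
    raised_cosine(u, b1 / m, h, A) +
    raised_cosine(u, (b1 + d) / m, h, -0.8 * A) +
    raised_cosine(u, b2 / m, h, A) +
    raised_cosine(u, (b2 + d) / m, h, -0.7 * A)

  base_v <- g * (1 - ramp01(u, 0.05, 0.13)) * (u <= 0.20) +
    g * ramp01(u, 0.27, 0.35) * (u > 0.20)
  vert <- base_v +
    raised_cosine(u, (b1 - d) / m, h, 0.9 * A) +
    raised_cosine(u, b1 / m, h, -A) +
    raised_cosine(u, b2 / m, h, A) +
    raised_cosine(u, (b2 + d) / m, h, -(0.8 * A + g)) +
    raised_cosine(u, sub / m, h, 0.35 * A)

  gyr_cor <- raised_cosine(u, 0.10, 0.07, 0.5 * G) +
    raised_cosine(u, 0.38, 0.13, G) +
    raised_cosine(u, 0.58, 0.06, -0.6 * G)
  acc_cor <- 0.3 * A * (raised_cosine(u, b1 / m, 0.05, 1) -
                          raised_cosine(u, b2 / m, 0.05, 1))

  list(
    channels = cbind(acc_cor = acc_cor, acc_sag = sag, acc_vert = vert,
                     gyr_cor = gyr_cor, gyr_sag = 0.3 * gyr_cor,
                     gyr_vert = -0.25 * gyr_cor),
    events = list(
      b1 = b1, b2 = b2, stance_begin = st,
      sag_peak_left = b1, sag_valley_left = b1 + d,
      vert_peak_left = b1 - d, vert_valley_left = b1,
      sag_peak_right = b2, sag_valley_right = b2 + d,
      vert_peak_right = b2, vert_valley_right = b2 + d),
    amplitude = A)
}

# static (stance) channel values: everything at rest except gravity
static_row <- function() {
  c(acc_cor = 0, acc_sag = 0, acc_vert = KERNEL$gravity,
    gyr_cor = 0, gyr_sag = 0, gyr_vert = 0)
}

#' Configuration for the synthetic walk generator
#'
#' @param n_strides number of full strides (>= 1).
#' @param cadence_hz stride rate in strides per second; a single value, or a
#'   vector of length `n_strides`. Self-selected walking cadences are about
#'   0.7 (slow), 0.9 (middle) and 1.1 (fast) strides/s.
#' @param speed_profile `"constant"`, `"alternating"` (strides alternate
#'   between the ends of `cadence_range`), or `"ramp"` (linear sweep across
#'   `cadence_range`). Ignored when `cadence_hz` is already a vector.
#' @param cadence_range length-2 numeric, used by the alternating and ramp
#'   profiles; defaults to `cadence_hz * c(0.85, 1.15)`.
#' @param sample_rate_hz IMU sampling rate (default 100 Hz).
#' @param noise_sd additive white Gaussian noise, as a fraction of the
#'   per-stride signal amplitude (0 = noise-free).
#' @param include_half_stride append a terminal "half-stride": the first
#'   half of the stride kernel followed by quiescence, as occurs when a
#'   walking bout ends.
#' @param seed integer seed; the generated walk is bitwise-identical for
#'   equal configurations.
#' @param length_map function from a full-stride noise-free feature vector
#'   (see [compute_features()]) to the true stride length in metres; the
#'   default is affine in the vertical Weinberg term,
#'   `1.0 * vertical_weinberg - 1.1`.
#' @param length_noise_sd standard deviation (metres) of the Gaussian noise
#'   added to the mapped stride length.
#' @param tail_s quiescent tail duration (seconds) appended after the last
#'   stride when `include_half_stride` is set.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(n_strides, cadence_hz = 0.9,
                        speed_profile = c("constant", "alternating", "ramp"),
                        cadence_range = NULL, sample_rate_hz = 100,
                        noise_sd = 0, include_half_stride = FALSE,
                        seed = 1L, length_map = NULL,
                        length_noise_sd = 0.03, tail_s = 1) {
  speed_profile <- match.arg(speed_profile)
  n_strides <- as.integer(n_strides)
  if (n_strides < 1L) stop("n_strides must be >= 1", call. = FALSE)
  if (any(cadence_hz <= 0) || sample_rate_hz <= 0 || noise_sd < 0)
    stop("cadence, sample rate must be positive; noise_sd >= 0",
         call. = FALSE)
  if (length(cadence_hz) == 1L) {
    cadence_hz <- switch(speed_profile,
      constant = rep(cadence_hz, n_strides),
      alternating = {
        rng <- cadence_range %||% (cadence_hz * c(0.85, 1.15))
        rep_len(rng, n_strides)
      },
      ramp = {
        rng <- cadence_range %||% (cadence_hz * c(0.85, 1.15))
        seq(rng[1], rng[2], length.out = n_strides)
      })
  } else if (length(cadence_hz) != n_strides) {
    stop("cadence_hz must be scalar or length n_strides", call. = FALSE)
  }
  structure(list(n_strides = n_strides, cadence_hz = cadence_hz,
                 sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
                 include_half_stride = isTRUE(include_half_stride),
                 seed = as.integer(seed),
                 length_map = length_map %||% default_length_map,
                 length_noise_sd = length_noise_sd, tail_s = tail_s),
            class = "walk_config")
}

default_length_map <- function(features) {
  1.0 * features[["vertical_weinberg"]] - 1.1
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default channel-role map
#'
#' The conventional CSV layout `acc_x/acc_y/acc_z, gyr_x/gyr_y/gyr_z` with
#' x = coronal, y = sagittal, z = vertical. Used by the synthetic generator
#' and as the default for [load_recording()] workflows.
#' @export
DEFAULT_CHANNEL_MAP <- list(
  accel = c(coronal = "acc_x", sagittal = "acc_y", vertical = "acc_z"),
  gyro = c(coronal = "gyr_x", sagittal = "gyr_y", vertical = "gyr_z"))

#' Generate a synthetic foot-IMU walk with ground truth
#'
#' Builds a contiguous stream of per-stride kernels (see package vignette
#' for the waveform model), adds seeded white Gaussian noise scaled to the
#' per-stride amplitude, and returns the recording together with the
#' ground-truth stride intervals, gait-phase labels, per-stride lengths,
#' and the planted major peak-valley-pair indices per channel.
#'
#' @param cfg a [walk_config()].
#' @return An object of class `synthetic_walk`: list with `recording`
#'   (an `imu_recording`), `truth` (an [annotation_set()]; phases are
#'   labeled for full strides only), `injected_events` (data.frame of
#'   planted indices in recording coordinates), and `config`.
#' @export
generate_walk <- function(cfg) {
  stopifnot(inherits(cfg, "walk_config"))
  fs <- cfg$sample_rate_hz
  kernels <- lapply(cfg$cadence_hz, function(cad)
    stride_kernel(round(fs / cad), cad))

  blocks <- list(); strides <- list(); phases <- list()
  events <- list(); lengths <- numeric(0); noise_sds <- numeric(0)
  offset <- 0L
  for (k in seq_along(kernels)) {
    kr <- kernels[[k]]
    m <- nrow(kr$channels)
    ev <- kr$events
    strides[[k]] <- data.frame(start = offset, end = offset + m)
    phases[[k]] <- data.frame(
      phase = c("push_off", "swing", "heel_strike", "stance"),
      start = offset + c(0L, ev$b1, ev$b2, ev$stance_begin),
      end = offset + c(ev$b1, ev$b2, ev$stance_begin, m))
    events[[k]] <- data.frame(stride = k,
      c(list(cadence_hz = cfg$cadence_hz[k]),
        lapply(ev, function(i) offset + i)))
    feats <- kernel_features(kr, cfg$cadence_hz[k])
    lengths <- c(lengths, cfg$length_map(feats))
    blocks[[length(blocks) + 1L]] <- kr$channels
    noise_sds <- c(noise_sds, rep(cfg$noise_sd * kr$amplitude, m))
    offset <- offset + m
  }

  half_start <- NA_integer_
  if (cfg$include_half_stride) {
    cad <- cfg$cadence_hz[cfg$n_strides]
    kr <- stride_kernel(round(fs / cad), cad)
    m <- nrow(kr$channels)
    half_m <- m %/% 2L
    quiet <- matrix(rep(static_row(), m - half_m + round(cfg$tail_s * fs)),
                    ncol = 6, byrow = TRUE,
                    dimnames = list(NULL, names(static_row())))
    half <- rbind(kr$channels[seq_len(half_m), , drop = FALSE], quiet)
    # short cosine fade into the static values at the truncation point
    fade <- 5L
    w <- 0.5 * (1 + cos(pi * seq_len(fade) / fade))
    rows <- seq.int(half_m - fade + 1L, half_m)
    half[rows, ] <- w * half[rows, ] +
      (1 - w) * matrix(rep(static_row(), fade), ncol = 6, byrow = TRUE)
    half_start <- offset
    strides[[length(strides) + 1L]] <-
      data.frame(start = offset, end = offset + half_m)
    lengths <- c(lengths, 0.5 * cfg$length_map(kernel_features(kr, cad)))
    blocks[[length(blocks) + 1L]] <- half
    noise_sds <- c(noise_sds, rep(cfg$noise_sd * kr$amplitude, nrow(half)))
    offset <- offset + nrow(half)
  }

  X <- do.call(rbind, blocks)
  n <- nrow(X)
  truth_lengths <- lengths
  walk <- with_seed(cfg$seed, {
    if (cfg$noise_sd > 0) {
      X[, 1:3] <- X[, 1:3] + stats::rnorm(3L * n, 0, rep(noise_sds, 3))
      gyro_scale <- KERNEL$gyro_amp(1) / KERNEL$accel_amp(1)
      X[, 4:6] <- X[, 4:6] +
        stats::rnorm(3L * n, 0, gyro_scale * rep(noise_sds, 3))
    }
    if (cfg$length_noise_sd > 0)
      truth_lengths <- truth_lengths +
        stats::rnorm(length(truth_lengths), 0, cfg$length_noise_sd)
    list(X = X, lengths = truth_lengths)
  })

  accel <- walk$X[, 1:3]; colnames(accel) <- c("acc_x", "acc_y", "acc_z")
  gyro <- walk$X[, 4:6]; colnames(gyro) <- c("gyr_x", "gyr_y", "gyr_z")
  rec <- imu_recording(timestamps = (seq_len(n) - 1L) / fs,
                       accel = accel, gyro = gyro,
                       channel_map = DEFAULT_CHANNEL_MAP,
                       sample_rate_hz = fs)
  truth <- annotation_set(
    strides = do.call(rbind, strides),
    phases = do.call(rbind, phases),
    stride_lengths = walk$lengths,
    meta = list(length_unit = "m", sample_rate_hz = fs,
                cadence_hz = cfg$cadence_hz, seed = cfg$seed,
                noise_sd = cfg$noise_sd, half_stride_start = half_start))
  structure(list(recording = rec, truth = truth,
                 injected_events = do.call(rbind, events), config = cfg),
            class = "synthetic_walk")
}

# full-stride features of the noise-free kernel, for the length map
kernel_features <- function(kr, cadence) {
  sag <- kr$channels[, "acc_sag"]; vert <- kr$channels[, "acc_vert"]
  mag <- sqrt(kr$channels[, "acc_cor"]^2 + sag^2 + vert^2)
  feats <- c(
    channel_feature_set(sag, "sagittal"),
    channel_feature_set(vert, "vertical"),
    channel_feature_set(mag, "magnitude"))
  c(feats, cadence = cadence)
}

#' @export
print.synthetic_walk <- function(x, ...) {
  cat(sprintf(
    "<synthetic_walk: %d strides%s, %d samples @ %g Hz, noise %.3g>\n",
    x$config$n_strides,
    if (x$config$include_half_stride) " + half-stride" else "",
    n_samples(x$recording), x$config$sample_rate_hz, x$config$noise_sd))
  invisible(x)
}

#' Generate a grid of synthetic walks with a manifest
#'
#' @param cadences numeric vector of cadences (strides/s), e.g.
#'   `c(0.7, 0.9, 1.1)` for slow/middle/fast.
#' @param seeds integer vector of seeds; one walk is generated per
#'   (cadence, seed) combination.
#' @param ... further arguments passed to [walk_config()] (e.g. `n_strides`,
#'   `noise_sd`).
#' @return List with `walks` (list of `synthetic_walk`) and `manifest`
#'   (data.frame with one row per walk: cadence, seed, stride count, sample
#'   count), suitable for reproducing every walk.
#' @export
generate_dataset <- function(cadences, seeds, ...) {
  if (!length(cadences) || !length(seeds))
    stop("cadence grid and seeds must be non-empty", call. = FALSE)
  grid <- expand.grid(cadence = cadences, seed = seeds)
  walks <- lapply(seq_len(nrow(grid)), function(i) {
    generate_walk(walk_config(cadence_hz = grid$cadence[i],
                              seed = grid$seed[i], ...))
  })
  manifest <- data.frame(
    grid,
    n_strides = vapply(walks, function(w) w$config$n_strides, integer(1)),
    n_samples = vapply(walks, function(w) n_samples(w$recording),
                       integer(1)))
  list(walks = walks, manifest = manifest)
}
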