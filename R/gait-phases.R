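# Division of each stride into stance, push-off, swing and heel-strike via
# major peak-valley-pair analysis of sagittal and vertical acceleration.
#
# Rationale: gait-phase transitions are abrupt changes in the foot-ground
# interaction force. On the sagittal and vertical accelerometer channels
# they appear as a dominant peak followed by a valley with a zero crossing
# in between (the "major peak-valley pair"). Between two stance phases the
# extrema concentrate in two clusters: the left cluster carries push-off
# evidence, the right cluster heel-strike evidence.

#' Gait-segmentation configuration
#'
#' @param preprocess_window odd moving-mean window (samples) applied before
#'   signed squaring; suppresses high-frequency sensor noise.
#' @param stance_window sliding-window width (samples) for stance detection;
#'   `NULL` selects 25 ms of samples (at least 3, forced odd).
#' @param var_frac,iqr_frac stance thresholds, relative to the stride-wide
#'   variance / interquartile range of the preprocessed signal. Relative
#'   thresholds keep the detector usable across walking speeds, where
#'   absolute thresholds fail.
#' @param prominence_frac minimum extremum prominence as a fraction of the
#'   preprocessed signal range.
#' @param merge_ratio,merge_window peak-valley-pair merge rule: a secondary
#'   zero-crossing pair whose span exceeds `merge_ratio` times the major span
#'   and whose peak lies within `merge_window` samples of the major valley is
#'   merged into the major pair.
#' @param kmeans_eps,kmeans_max_iter stopping rule for the deterministic 1-D
#'   2-means used to split extrema into push-off/heel-strike clusters.
#' @param outlier_sd,min_refs leave-one-out outlier rejection drops a
#'   reference farther than `outlier_sd` standard deviations from the mean of
#'   the others; skipped when fewer than `min_refs` references are available
#'   (the SD of two points is degenerate).
#' @param stance_widen increasing threshold-widening factors tried in order
#'   when no sufficiently long run of quiet windows qualifies at the base
#'   thresholds (noisy recordings).
#' @param cluster_peaks_only if `TRUE`, only peaks (not valleys) enter the
#'   extrema clustering.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(preprocess_window = 5L, stance_window = NULL,
                        var_frac = 0.02, iqr_frac = 0.10,
                        prominence_frac = 0.05,
                        merge_ratio = 0.5, merge_window = 5L,
                        kmeans_eps = 0.5, kmeans_max_iter = 50L,
                        outlier_sd = 3, min_refs = 4L,
                        stance_widen = c(1, 2, 4, 8),
                        cluster_peaks_only = FALSE) {
  structure(list(preprocess_window = as.integer(preprocess_window),
                 stance_window = stance_window,
                 stance_widen = stance_widen,
                 var_frac = var_frac, iqr_frac = iqr_frac,
                 prominence_frac = prominence_frac,
                 merge_ratio = merge_ratio,
                 merge_window = as.integer(merge_window),
                 kmeans_eps = kmeans_eps,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 outlier_sd = outlier_sd, min_refs = as.integer(min_refs),
                 cluster_peaks_only = isTRUE(cluster_peaks_only)),
            class = "gait_config")
}

#' Mean-filter and sign-preserving squaring
#'
#' Applies a moving mean with replication-padded edges, then deflates the
#' signal by squaring and restoring the original sign:
#' `y_i = sign(m_i) * m_i^2`. Squaring amplifies the dynamic-phase
#' excursions relative to the near-zero stance segments, making the static
#' phase easier to isolate.
#'
#' @param signal numeric vector.
#' @param window odd moving-mean window width (samples).
#' @return Numeric vector, same length as `signal`.
#' @export
preprocess <- function(signal, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1", call. = FALSE)
  m <- if (window == 1L) as.numeric(signal)
       else rowMeans(window_matrix(as.numeric(signal), (window - 1L) %/% 2L))
  sign(m) * m^2
}

odd_window <- function(x, minimum = 3L) {
  w <- max(minimum, as.integer(round(x)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

rolling_stat <- function(x, width, fun) {
  n <- length(x) - width + 1L
  vapply(seq_len(n), function(i) fun(x[i:(i + width - 1L)]), numeric(1))
}

#' Detect the stance phase within a stride
#'
#' Slides a short window over the preprocessed sagittal and vertical
#' acceleration of the stride; positions where the variance AND the
#' interquartile range on both channels fall below their (stride-relative)
#' thresholds qualify as static. The latest maximal run of qualifying
#' positions is returned as the stance interval, since stance closes the
#' stride cycle. A quiet mid-swing segment can also qualify, but taking the
#' latest run keeps the detector anchored to the terminal stance.
#'
#' @param rec an `imu_recording`.
#' @param stride a [sample_interval()] in recording coordinates.
#' @param cfg a [gait_config()].
#' @return An object of class `stance_phase` (interval in recording
#'   coordinates plus the four volatility statistics over it), or `NULL`
#'   when no window qualifies ("no stance found"; the caller may widen the
#'   thresholds).
#' @export
detect_stance <- function(rec, stride, cfg = gait_config()) {
  stride <- as_interval(stride)
  w <- if (is.null(cfg$stance_window))
    odd_window(0.025 * rec$sample_rate_hz) else as.integer(cfg$stance_window)
  m <- interval_length(stride)
  if (m < w)
    stop(sprintf("stride length %d below stance window %d", m, w),
         call. = FALSE)
  seg <- slice_recording(rec, stride)
  ps <- preprocess(channel(seg, "sagittal"), cfg$preprocess_window)
  pv <- preprocess(channel(seg, "vertical"), cfg$preprocess_window)

  iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  rv_s <- rolling_stat(ps, w, stats::var)
  rv_v <- rolling_stat(pv, w, stats::var)
  ri_s <- rolling_stat(ps, w, iqr)
  ri_v <- rolling_stat(pv, w, iqr)

  # thresholds are widened progressively until some window qualifies; under
  # noise the qualifying windows inside the true stance fragment, so nearby
  # fragments (gaps up to 10% of the stride) are merged before the latest
  # cluster is taken
  qualifying <- function(factor) {
    which(rv_s < factor * cfg$var_frac * stats::var(ps) &
            rv_v < factor * cfg$var_frac * stats::var(pv) &
            ri_s < factor * cfg$iqr_frac * iqr(ps) &
            ri_v < factor * cfg$iqr_frac * iqr(pv))
  }
  # stance closes the stride cycle, so the qualifying cluster must reach
  # near the stride end; a factor whose quiet windows lie only mid-stride
  # (a swing lull) is widened past. The last few window positions are
  # contaminated by the mean filter's replication padding (it flattens any
  # signal there), so they are not considered; a run reaching the
  # considered tail is extended back to the stride end.
  gap_tol <- max(w, round(0.10 * m))
  pad <- cfg$preprocess_window %/% 2L
  n_eff <- m - w + 1L - pad
  pos <- integer(0)
  for (f in cfg$stance_widen) {
    cand <- qualifying(f)
    cand <- cand[cand <= n_eff]
    if (!length(pos) && length(cand)) pos <- cand
    if (length(cand) && cand[length(cand)] >= n_eff - gap_tol) {
      pos <- cand
      break
    }
  }
  if (!length(pos)) return(NULL)
  brk <- which(diff(pos) > gap_tol)
  first <- if (length(brk)) pos[max(brk) + 1L] else pos[1L]
  run <- c(first, pos[length(pos)])

  # window positions run[1]..run[2] cover samples pos .. pos+w-1
  lo <- run[1] - 1L                      # 0-based, relative to stride
  hi <- if (run[2] >= n_eff) m else run[2] - 1L + w   # exclusive
  iv <- sample_interval(stride$start + lo, stride$start + hi)
  rel <- (lo + 1L):hi
  structure(list(interval = iv,
                 variance_s = stats::var(ps[rel]),
                 variance_v = stats::var(pv[rel]),
                 iqr_s = iqr(ps[rel]), iqr_v = iqr(pv[rel])),
            class = "stance_phase")
}

#' Find strict local extrema above a prominence floor
#'
#' Plateaus count once, at their first index. Prominence of a peak is its
#' height above the higher of the two lowest points separating it from
#' higher terrain on either side (the standard topographic definition);
#' valleys are peaks of the negated signal.
#'
#' @param signal numeric vector.
#' @param min_prominence minimum prominence; `NULL` selects
#'   `prominence_frac * diff(range(signal))` from `cfg`.
#' @param cfg a [gait_config()].
#' @return List with 0-based integer vectors `peaks` and `valleys`.
#' @export
find_extrema <- function(signal, min_prominence = NULL, cfg = gait_config()) {
  if (is.null(min_prominence))
    min_prominence <- cfg$prominence_frac * diff(range(signal))
  list(peaks = local_maxima(signal, min_prominence),
       valleys = local_maxima(-signal, min_prominence))
}

local_maxima <- function(x, min_prom) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  run_start <- cumsum(c(1L, r$lengths[-k]))
  is_max <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                r$values[2:(k - 1)] > r$values[3:k], FALSE)
  idx <- run_start[is_max]            # first index of each plateau (1-based)
  if (!length(idx)) return(integer(0))
  keep <- vapply(idx, function(i) prominence(x, i) >= min_prom, logical(1))
  as.integer(idx[keep] - 1L)
}

prominence <- function(x, i) {
  left <- x[seq_len(i - 1L)]
  right <- x[seq.int(i + 1L, length(x))]
  base_side <- function(side) {
    higher <- which(side > x[i])
    if (length(higher)) min(side[seq.int(min(higher), length(side))])
    else min(side)
  }
  # walk outward to the first strictly higher sample (or the edge); the
  # lowest sample on that stretch is the side's base
  lmin <- {
    higher <- which(left > x[i])
    if (length(higher)) min(left[seq.int(max(higher), length(left))])
    else min(left)
  }
  rmin <- {
    higher <- which(right > x[i])
    if (length(higher)) min(right[seq_len(min(higher))]) else min(right)
  }
  x[i] - max(lmin, rmin)
}

#' Split extrema indices into push-off and heel-strike clusters
#'
#' Deterministic 1-D 2-means with the centers initialized to the enclosing
#' stance boundaries: points between two stances fall into a left cluster
#' (push-off evidence) and a right cluster (heel-strike evidence).
#' Assignment uses squared distance with ties going left; iteration stops
#' after `kmeans_max_iter` rounds or when both centers move less than
#' `kmeans_eps` samples. No randomness is involved.
#'
#' @param indices integer extrema indices (0-based), all strictly between
#'   the two stance bounds.
#' @param last_stance_end,current_stance_begin 0-based cluster-center
#'   initializers: end of the previous stance and start of the upcoming one.
#' @param cfg a [gait_config()].
#' @return List with integer vectors `left` and `right` (either may be
#'   empty; both empty means no evidence).
#' @export
cluster_extrema <- function(indices, last_stance_end, current_stance_begin,
                            cfg = gait_config()) {
  indices <- sort(as.integer(indices))
  if (!length(indices)) return(list(left = integer(0), right = integer(0)))
  c0 <- as.numeric(last_stance_end)
  c1 <- as.numeric(current_stance_begin)
  for (iter in seq_len(cfg$kmeans_max_iter)) {
    to_left <- (indices - c0)^2 <= (indices - c1)^2   # tie -> left
    c0_new <- if (any(to_left)) mean(indices[to_left]) else c0
    c1_new <- if (any(!to_left)) mean(indices[!to_left]) else c1
    shifted <- abs(c0_new - c0) >= cfg$kmeans_eps ||
      abs(c1_new - c1) >= cfg$kmeans_eps
    c0 <- c0_new; c1 <- c1_new
    if (!shifted) break
  }
  to_left <- (indices - c0)^2 <= (indices - c1)^2
  list(left = indices[to_left], right = indices[!to_left])
}

#' Find the major peak-valley pair of a signal segment
#'
#' Pairs each peak with the nearest valley that follows it. Among pairs
#' whose signal crosses zero between peak and valley, the pair with the
#' largest span (peak value minus valley value) is the major pair. A
#' secondary zero-crossing pair whose span exceeds `merge_ratio` of the
#' major span and whose peak lies within `merge_window` samples of the
#' major valley merges with it into a pair spanning (first peak, second
#' valley); the merge stabilizes the pair on noisy sequences where one
#' force transient splits into two excursions.
#'
#' @param signal numeric vector (typically a preprocessed stride slice).
#' @param peaks,valleys 0-based extrema indices (e.g. one cluster's share of
#'   [find_extrema()] output).
#' @param cfg a [gait_config()].
#' @param channel_role metadata tag stored on the result.
#' @param require_crossing if `FALSE`, the zero-crossing condition is waived
#'   (fallback for segments that never cross zero).
#' @return A `peak_valley_pair` (list with `peak_index`, `valley_index`,
#'   `span`, `channel_role`) or `NULL` when no qualifying pair exists.
#' @export
find_major_pvp <- function(signal, peaks, valleys, cfg = gait_config(),
                           channel_role = NA_character_,
                           require_crossing = TRUE) {
  peaks <- sort(as.integer(peaks)); valleys <- sort(as.integer(valleys))
  if (!length(peaks) || !length(valleys)) return(NULL)
  pairs <- lapply(peaks, function(p) {
    after <- valleys[valleys > p]
    if (!length(after)) return(NULL)
    v <- after[1L]
    seg <- signal[(p + 1L):(v + 1L)]
    list(peak = p, valley = v, span = signal[p + 1L] - signal[v + 1L],
         crossing = any(seg[-1L] * seg[-length(seg)] <= 0))
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) return(NULL)
  if (require_crossing) pairs <- Filter(function(pr) pr$crossing, pairs)
  if (!length(pairs)) return(NULL)
  spans <- vapply(pairs, `[[`, numeric(1), "span")
  major <- pairs[[which.max(spans)]]
  # merge rule
  for (pr in pairs) {
    if (pr$peak == major$peak) next
    if (pr$span > cfg$merge_ratio * major$span &&
        abs(pr$peak - major$valley) < cfg$merge_window) {
      first <- if (pr$peak < major$peak) pr else major
      second <- if (pr$peak < major$peak) major else pr
      major <- list(peak = first$peak, valley = second$valley,
                    span = signal[first$peak + 1L] -
                      signal[second$valley + 1L],
                    crossing = TRUE)
      break
    }
  }
  structure(list(peak_index = major$peak, valley_index = major$valley,
                 span = major$span, channel_role = channel_role),
            class = "peak_valley_pair")
}

# first difference with trailing replication: same length as input
first_difference <- function(x) {
  d <- diff(x)
  c(d, d[length(d)])
}

#' Zero-crossing reference from a derivative sequence
#'
#' Peaks of a signal correspond to negative zero crossings of its
#' derivative, valleys to positive crossings. Returns the crossing of the
#' requested polarity nearest in time to the matching extremum of a
#' peak-valley pair, as an additional gait-boundary reference.
#'
#' @param deriv numeric derivative sequence (first difference, trailing
#'   value replicated).
#' @param pvp a [find_major_pvp()] result.
#' @param polarity `"negative"` (reference extremum: the pair's peak) or
#'   `"positive"` (the pair's valley).
#' @return 0-based crossing index, or `NULL` when no crossing of the
#'   requested polarity exists (the reference is omitted).
#' @export
zero_crossing_refs <- function(deriv, pvp,
                               polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  n <- length(deriv)
  prev <- deriv[-n]; curr <- deriv[-1L]
  hits <- if (polarity == "negative") which(prev > 0 & curr <= 0)
          else which(prev < 0 & curr >= 0)   # 1-based position of `curr`
  if (!length(hits)) return(NULL)
  anchor <- if (polarity == "negative") pvp$peak_index else pvp$valley_index
  idx0 <- as.integer(hits)                   # 0-based crossing index
  idx0[which.min(abs(idx0 - anchor))]
}

#' Leave-one-out outlier rejection for boundary references
#'
#' For each reference index, a normal fit (mean and SD) is computed on the
#' remaining references; the reference is flagged when it lies more than
#' `outlier_sd` standard deviations from that mean. Rejection is skipped
#' with fewer than `min_refs` references, and never empties the set.
#'
#' @param refs numeric vector of reference indices.
#' @param cfg a [gait_config()].
#' @return The surviving references, in input order.
#' @export
reject_outliers <- function(refs, cfg = gait_config()) {
  refs <- as.numeric(refs)
  if (length(refs) < cfg$min_refs) return(refs)
  flagged <- vapply(seq_along(refs), function(i) {
    others <- refs[-i]
    s <- stats::sd(others)
    abs(refs[i] - mean(others)) > cfg$outlier_sd * s
  }, logical(1))
  if (all(flagged)) return(refs)
  refs[!flagged]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

boundary_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gaitstride_error")))
}

#' Locate the two dynamic gait boundaries of one stride
#'
#' Detects the stance phase, clusters the extrema of the preprocessed
#' sagittal and vertical acceleration between the previous stance end and
#' the upcoming stance begin, extracts each cluster's major peak-valley
#' pair per channel, and fuses the per-channel references into the
#' push-off/swing boundary (sagittal peak + vertical valley) and the
#' swing/heel-strike boundary (sagittal peak + vertical peak). In
#' `four_ref` mode the nearest derivative zero crossings join the reference
#' set and leave-one-out outlier rejection is applied before averaging.
#'
#' @param rec an `imu_recording`.
#' @param stride a [sample_interval()].
#' @param mode `"two_ref"` or `"four_ref"`.
#' @param cfg a [gait_config()].
#' @return List with elements `push_off_swing` and `swing_heel_strike`
#'   (each a `boundary_estimate`: references used, fused index in recording
#'   coordinates, boundary kind) and `stance` (the [detect_stance()] result).
#' @export
locate_boundaries <- function(rec, stride, mode = c("four_ref", "two_ref"),
                              cfg = gait_config()) {
  mode <- match.arg(mode)
  stride <- as_interval(stride)
  stance <- detect_stance(rec, stride, cfg)
  if (is.null(stance))
    boundary_error("no stance found in stride", "gaitstride_no_stance")

  seg <- slice_recording(rec, stride)
  ps <- preprocess(channel(seg, "sagittal"), cfg$preprocess_window)
  pv <- preprocess(channel(seg, "vertical"), cfg$preprocess_window)
  stance_rel <- stance$interval$start - stride$start  # 0-based, exclusive cap

  ex_s <- find_extrema(ps, cfg = cfg)
  ex_v <- find_extrema(pv, cfg = cfg)
  in_window <- function(i) i[i > 0L & i < stance_rel]
  ex_s <- lapply(ex_s, in_window)
  ex_v <- lapply(ex_v, in_window)

  pool <- if (cfg$cluster_peaks_only) c(ex_s$peaks, ex_v$peaks)
          else c(ex_s$peaks, ex_s$valleys, ex_v$peaks, ex_v$valleys)
  cl <- cluster_extrema(pool, 0L, stance_rel, cfg)
  if (!length(cl$left) || !length(cl$right))
    boundary_error("extrema clustering produced an empty cluster",
                   "gaitstride_no_boundary")
  ranges <- list(left = range(cl$left), right = range(cl$right))

  # peaks must lie inside the cluster's index range; the paired valley may
  # follow the peak past the range edge (up to the valley cap), so that a
  # cluster boundary falling between a peak and its valley cannot orphan the
  # pair
  pvp_in <- function(sig, ex, rng, valley_cap, role) {
    peaks <- ex$peaks[ex$peaks >= rng[1] & ex$peaks <= rng[2]]
    valleys <- ex$valleys[ex$valleys >= rng[1] & ex$valleys < valley_cap]
    pvp <- find_major_pvp(sig, peaks, valleys, cfg, channel_role = role)
    if (is.null(pvp)) {
      pvp <- find_major_pvp(sig, peaks, valleys, cfg, channel_role = role,
                            require_crossing = FALSE)
      if (!is.null(pvp))
        warning(sprintf(
          "no zero-crossing pair on %s channel; using largest-span pair",
          role), call. = FALSE)
    }
    pvp
  }
  sag_l <- pvp_in(ps, ex_s, ranges$left, ranges$right[1], "sagittal")
  ver_l <- pvp_in(pv, ex_v, ranges$left, ranges$right[1], "vertical")
  sag_r <- pvp_in(ps, ex_s, ranges$right, stance_rel, "sagittal")
  ver_r <- pvp_in(pv, ex_v, ranges$right, stance_rel, "vertical")
  if (is.null(sag_l) && is.null(ver_l))
    boundary_error("no usable peak-valley pair in push-off cluster",
                   "gaitstride_no_boundary")
  if (is.null(sag_r) && is.null(ver_r))
    boundary_error("no usable peak-valley pair in heel-strike cluster",
                   "gaitstride_no_boundary")

  ds <- first_difference(ps)
  dv <- first_difference(pv)

  refs1 <- list()
  if (!is.null(sag_l))
    refs1$sag_acc <- sag_l$peak_index
  if (!is.null(ver_l))
    refs1$vert_acc <- ver_l$valley_index
  refs2 <- list()
  if (!is.null(sag_r))
    refs2$sag_acc <- sag_r$peak_index
  if (!is.null(ver_r))
    refs2$vert_acc <- ver_r$peak_index
  if (mode == "four_ref") {
    if (!is.null(sag_l))
      refs1$sag_deriv <- zero_crossing_refs(ds, sag_l, "negative")
    if (!is.null(ver_l))
      refs1$vert_deriv <- zero_crossing_refs(dv, ver_l, "positive")
    if (!is.null(sag_r))
      refs2$sag_deriv <- zero_crossing_refs(ds, sag_r, "negative")
    if (!is.null(ver_r))
      refs2$vert_deriv <- zero_crossing_refs(dv, ver_r, "negative")
    refs1 <- Filter(Negate(is.null), refs1)
    refs2 <- Filter(Negate(is.null), refs2)
  }

  fuse <- function(refs, kind) {
    idx <- unlist(refs)
    used <- if (mode == "four_ref") reject_outliers(idx, cfg) else idx
    fused_rel <- round_half_away(mean(used))
    structure(list(
      references = data.frame(source = names(refs),
                              index = stride$start + as.integer(idx)),
      n_rejected = length(idx) - length(used),
      fused_index = stride$start + as.integer(fused_rel),
      boundary_kind = kind), class = "boundary_estimate")
  }
  b1 <- fuse(refs1, "push_off/swing")
  b2 <- fuse(refs2, "swing/heel_strike")

  if (!(stride$start < b1$fused_index && b1$fused_index < b2$fused_index &&
        b2$fused_index < stance$interval$start))
    boundary_error(sprintf(
      "boundary ordering violated: %d < %d < %d < %d required",
      stride$start, b1$fused_index, b2$fused_index, stance$interval$start),
      "gaitstride_no_boundary")

  list(push_off_swing = b1, swing_heel_strike = b2, stance = stance)
}

#' Segment strides into the four gait phases
#'
#' For each stride the four phases tile it exactly:
#' `push_off = [stride_start, b1)`, `swing = [b1, b2)`,
#' `heel_strike = [b2, stance_begin)`, `stance = [stance_begin, stride_end)`.
#' Strides whose boundaries cannot be located are reported in the
#' diagnostics, never silently dropped.
#'
#' @param rec an `imu_recording`.
#' @param strides data.frame with `start`, `end` columns (0-based half-open),
#'   or a list of [sample_interval()] — e.g. the `matches` of [sdatw_match()].
#' @param mode `"two_ref"` or `"four_ref"`.
#' @param cfg a [gait_config()].
#' @return An object of class `gait_segmentation`: list with `phases`
#'   (data.frame `phase`, `start`, `end`), `boundaries` (per successful
#'   stride: stride bounds, both fused boundaries, stance begin),
#'   `diagnostics` (per failed stride: bounds and reason), and `mode`.
#' @export
segment_gait <- function(rec, strides, mode = c("four_ref", "two_ref"),
                         cfg = gait_config()) {
  mode <- match.arg(mode)
  strides <- intervals_df(strides)
  phases <- list(); bounds <- list(); diag <- list()
  for (k in seq_len(nrow(strides))) {
    iv <- sample_interval(strides$start[k], strides$end[k])
    res <- tryCatch(locate_boundaries(rec, iv, mode, cfg),
                    gaitstride_error = function(e) e)
    if (inherits(res, "error")) {
      diag[[length(diag) + 1L]] <- data.frame(
        start = iv$start, end = iv$end, reason = conditionMessage(res))
      next
    }
    b1 <- res$push_off_swing$fused_index
    b2 <- res$swing_heel_strike$fused_index
    st <- res$stance$interval$start
    phases[[length(phases) + 1L]] <- data.frame(
      phase = c("push_off", "swing", "heel_strike", "stance"),
      start = c(iv$start, b1, b2, st),
      end = c(b1, b2, st, iv$end))
    bounds[[length(bounds) + 1L]] <- data.frame(
      stride_start = iv$start, stride_end = iv$end,
      push_off_swing = b1, swing_heel_strike = b2, stance_begin = st)
  }
  empty_diag <- data.frame(start = integer(0), end = integer(0),
                           reason = character(0))
  structure(list(
    phases = if (length(phases)) do.call(rbind, phases)
             else data.frame(phase = character(0), start = integer(0),
                             end = integer(0)),
    boundaries = if (length(bounds)) do.call(rbind, bounds) else NULL,
    diagnostics = if (length(diag)) do.call(rbind, diag) else empty_diag,
    mode = mode), class = "gait_segmentation")
}

#' @export
print.gait_segmentation <- function(x, ...) {
  n_ok <- if (is.null(x$boundaries)) 0L else nrow(x$boundaries)
  cat(sprintf(
    "<gait_segmentation (%s): %d strides segmented, %d failed>\n",
    x$mode, n_ok, nrow(x$diagnostics)))
  invisible(x)
}
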