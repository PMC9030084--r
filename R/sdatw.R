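# Stride-template construction and threshold-free subsequence matching
# (SDATW: subsequence DTW over per-sample neighborhood features with
# start-point propagation). All sample indices in this file follow the
# package convention: 0-based, half-open intervals.

#' SDATW configuration
#'
#' Tunables for stride matching. The matcher compares per-sample
#' neighborhood descriptors, not raw samples, which smooths the accumulated
#' distance and reduces sensitivity to sensor noise.
#'
#' @param w neighborhood half-width in samples (window `i-w .. i+w`,
#'   replication-padded at the edges).
#' @param features `"default"` (mean gradient, amplitude range, window mean)
#'   or `"haar"` (two-level Haar decomposition coefficients of the window).
#' @param normalize if `TRUE`, each sequence's descriptors are divided by
#'   that sequence's raw amplitude range, making detected boundaries
#'   invariant to rescaling the stream by any positive constant.
#' @param competitor_window window (samples) within which a candidate match
#'   end must beat all competitors; `NULL` means `L/2` for template length
#'   `L`.
#' @param min_match_frac matches shorter than `min_match_frac * L` samples
#'   are suppressed as spurious. The default 1/3 keeps terminal half-strides
#'   (about `L/2` long) while rejecting single-peak noise.
#' @param sensor,channel_role which channel to match when the stream is an
#'   `imu_recording` (default: gyroscope coronal axis).
#' @return A list of class `sdatw_config`.
#' @export
sdatw_config <- function(w = 5L, features = c("default", "haar"),
                         normalize = FALSE, competitor_window = NULL,
                         min_match_frac = 1 / 3,
                         sensor = "gyro", channel_role = "coronal") {
  features <- match.arg(features)
  if (w < 1L) stop("neighborhood half-width w must be >= 1", call. = FALSE)
  structure(list(w = as.integer(w), features = features,
                 normalize = isTRUE(normalize),
                 competitor_window = competitor_window,
                 min_match_frac = min_match_frac,
                 sensor = sensor, channel_role = channel_role),
            class = "sdatw_config")
}

#' Build a stride template by length-normalized averaging
#'
#' Each input stride is linearly resampled to a common length `L`; the
#' template is the column-wise mean of the resampled strides. Averaging many
#' strides from different subjects and speeds yields a speed- and
#' subject-neutral matching reference.
#'
#' @param strides list of numeric vectors (one per stride, each length >= 2).
#' @param L target template length in samples; default is the median input
#'   stride length.
#' @param channel_role which signal role the template matches (metadata).
#' @return An object of class `stride_template`: list with `values`
#'   (length-`L` numeric), `channel_role`, and `L`.
#' @export
build_template <- function(strides, L = NULL, channel_role = "coronal") {
  if (!length(strides)) stop("need at least one stride", call. = FALSE)
  lens <- vapply(strides, length, integer(1))
  if (any(lens < 2L)) stop("each stride must have length >= 2", call. = FALSE)
  if (is.null(L)) L <- as.integer(round(stats::median(lens)))
  L <- as.integer(L)
  if (L < 2L) stop("template length L must be >= 2", call. = FALSE)
  xout <- seq(0, 1, length.out = L)
  resampled <- vapply(strides, function(s) {
    stats::approx(seq(0, 1, length.out = length(s)), s, xout = xout)$y
  }, numeric(L))
  values <- rowMeans(resampled)
  if (any(!is.finite(values)))
    stop("template contains non-finite values", call. = FALSE)
  structure(list(values = values, channel_role = channel_role, L = L),
            class = "stride_template")
}

#' @export
print.stride_template <- function(x, ...) {
  cat(sprintf("<stride_template: L = %d samples, channel role %s>\n",
              x$L, x$channel_role))
  invisible(x)
}

#' Write / read a stride template as JSON
#' @param template a [build_template()] result.
#' @param path JSON file path.
#' @return `path` (write) or a `stride_template` (read).
#' @export
write_template <- function(template, path) {
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(values = as.numeric(obj$values),
                 channel_role = obj$channel_role, L = as.integer(obj$L)),
            class = "stride_template")
}

# replication-padded window matrix: row i holds signal[(i-w)..(i+w)]
window_matrix <- function(signal, w) {
  n <- length(signal)
  cols <- lapply(-w:w, function(k) signal[pmin(pmax(seq_len(n) + k, 1L), n)])
  do.call(cbind, cols)
}

# two-level Haar averages/differences of a window resampled to 4 points
haar_descriptor <- function(W) {
  m <- ncol(W)
  pick <- round(seq(1, m, length.out = 4))
  X <- W[, pick, drop = FALSE]
  a1 <- (X[, 1] + X[, 2]) / 2; a2 <- (X[, 3] + X[, 4]) / 2
  d1 <- (X[, 1] - X[, 2]) / 2; d2 <- (X[, 3] - X[, 4]) / 2
  cbind((a1 + a2) / 2, (a1 - a2) / 2, d1, d2)
}

#' Per-sample neighborhood descriptor
#'
#' Computes the local descriptor SDATW matches on: by default the
#' concatenation of (mean gradient over `i-w..i+w`, amplitude range over the
#' window, window mean). Edges are handled by replication padding, so the
#' descriptor is defined for every sample.
#'
#' @param signal numeric vector.
#' @param i 0-based sample index, or `NULL` to return the full `n x k`
#'   descriptor matrix.
#' @param cfg an [sdatw_config()].
#' @return Numeric vector (single `i`) or matrix (all samples).
#' @export
neighborhood_features <- function(signal, i = NULL, cfg = sdatw_config()) {
  W <- window_matrix(signal, cfg$w)
  F <- if (cfg$features == "haar") {
    haar_descriptor(W)
  } else {
    m <- ncol(W)
    grad <- (W[, m] - W[, 1]) / (m - 1)
    rng <- do.call(pmax, as.data.frame(W)) - do.call(pmin, as.data.frame(W))
    cbind(grad, rng, rowMeans(W))
  }
  if (cfg$normalize) {
    span <- diff(range(signal))
    if (span > 0) F <- F / span
  }
  if (is.null(i)) return(unname(F))
  unname(F[i + 1L, ])
}

# Euclidean cost matrix between template-row and stream-sample descriptors
sdatw_cost <- function(stream_feat, template_feat) {
  # (L x k) vs (n x k) -> L x n
  L <- nrow(template_feat); n <- nrow(stream_feat)
  TT <- rowSums(template_feat^2)
  SS <- rowSums(stream_feat^2)
  G <- template_feat %*% t(stream_feat)
  sq <- outer(TT, SS, "+") - 2 * G
  sq[sq < 0] <- 0
  sqrt(sq)
}

#' Threshold-free subsequence stride matching (SDATW)
#'
#' Runs subsequence dynamic time warping of a stride template against a
#' continuous sensor stream, using per-sample neighborhood descriptors as
#' the local distance and propagating the warping-path start point through
#' the accumulated-distance recurrence. A match is emitted where the
#' accumulated distance at the final template row attains a minimum over all
#' path ends sharing the same start point; candidates are then compared with
#' local competitors, so no absolute distance threshold is involved.
#' Terminal "half-strides" (a truncated last stride followed by quiescence)
#' are captured because partial alignments that consume the remaining quiet
#' samples at the final template row stay cheap.
#'
#' @param stream numeric vector, or an `imu_recording` (the configured
#'   channel is extracted).
#' @param template a [build_template()] result.
#' @param cfg an [sdatw_config()].
#' @return An object of class `stride_matches`: a list with
#'   `matches` (data.frame `start`, `end`, `accumulated_distance`; 0-based
#'   half-open intervals, ordered and non-overlapping) and `paths` (list of
#'   0-based `(stream_index, template_index)` matrices).
#' @export
sdatw_match <- function(stream, template, cfg = sdatw_config()) {
  if (inherits(stream, "imu_recording"))
    stream <- channel(stream, cfg$channel_role, cfg$sensor)
  stream <- as.numeric(stream)
  L <- template$L
  if (L < 8L)
    stop("matching requires a template of length >= 8", call. = FALSE)
  n <- length(stream)
  if (n < L / 2)
    stop(sprintf("stream length %d shorter than L/2 = %g", n, L / 2),
         call. = FALSE)
  sf <- neighborhood_features(stream, NULL, cfg)
  tf <- neighborhood_features(template$values, NULL, cfg)
  cost <- sdatw_cost(sf, tf)
  dp <- .sdatw_dp(cost)
  A <- dp$D[L, ]
  S <- dp$start[L, ]

  # one candidate per start group: the end minimizing accumulated distance
  # (ties -> earliest end, so flat-cost extensions do not inflate matches)
  ends <- tapply(seq_len(n), S, function(idx) idx[which.min(A[idx])])
  ends <- as.integer(ends)
  cand <- data.frame(start = S[ends], end0 = ends - 1L, dist = A[ends],
                     raw_end0 = ends - 1L)
  cand$len <- cand$end0 - cand$start + 1L
  cand <- cand[cand$len >= cfg$min_match_frac * L, , drop = FALSE]

  # greedy acceptance by ascending accumulated distance; boundary jitter of
  # adjacent strides may overlap a few samples, so small overlaps (up to
  # L/4 per side) are trimmed rather than rejected
  comp <- cfg$competitor_window %||% (L / 2)
  max_trim <- L / 4
  cand <- cand[order(cand$dist, cand$end0), , drop = FALSE]
  accepted <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    ci <- cand[r, ]
    s <- ci$start; e <- ci$end0 + 1L   # half-open [s, e)
    ok <- TRUE
    if (nrow(accepted)) {
      for (a in seq_len(nrow(accepted))) {
        as <- accepted$start[a]; ae <- accepted$end0[a] + 1L
        if (s < ae && as < e) {            # overlapping = competitor
          # a competitor whose end lies within the competitor window is a
          # rival alignment of the same stride; the accepted (cheaper) one
          # already won
          if (abs(accepted$end0[a] - ci$end0) < comp) { ok <- FALSE; break }
          if (as <= s && ae >= e) { ok <- FALSE; break }   # swallowed
          if (as <= s) {                   # accepted on the left
            if (ae - s > max_trim) { ok <- FALSE; break }
            s <- ae
          } else {                         # accepted on the right
            if (e - as > max_trim) { ok <- FALSE; break }
            e <- as
          }
        }
      }
    }
    if (!ok || e - s < cfg$min_match_frac * L) next
    ci$start <- s; ci$end0 <- e - 1L
    accepted <- rbind(accepted, ci)
  }
  accepted <- accepted[order(accepted$start), , drop = FALSE]

  paths <- lapply(seq_len(nrow(accepted)), function(r) {
    p <- .sdatw_traceback(dp$pred, accepted$raw_end0[r])
    p[p[, 1] >= accepted$start[r] & p[, 1] <= accepted$end0[r], ,
      drop = FALSE]
  })
  matches <- data.frame(start = accepted$start,
                        end = accepted$end0 + 1L,
                        accumulated_distance = accepted$dist)
  rownames(matches) <- NULL
  structure(list(matches = matches, paths = paths, L = L),
            class = "stride_matches")
}

#' @export
print.stride_matches <- function(x, ...) {
  cat(sprintf("<stride_matches: %d matches (template L = %d)>\n",
              nrow(x$matches), x$L))
  if (nrow(x$matches)) print(utils::head(x$matches, 10))
  invisible(x)
}
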