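#' @useDynLib gaitstride, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var median quantile sd predict rnorm runif
#' @importFrom utils read.csv write.csv head tail
#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom jsonlite read_json write_json
#' @importFrom yaml read_yaml write_yaml
NULL

# ---------------------------------------------------------------------------
# Sample intervals
#
# All intervals in this package are half-open [start, end) index ranges with
# 0-based sample indices. 0-based half-open arithmetic makes phase tiling and
# temporal IoU exact: [a,b) and [b,c) tile [a,c) with no gap or overlap.
# Helpers convert to 1-based R subscripts only at the point of subsetting.
# ---------------------------------------------------------------------------

#' Create a sample interval
#'
#' A half-open index range `[start, end)` on a recording, with 0-based sample
#' indices. Sample intervals are the unit in which strides and gait phases
#' are expressed throughout the package.
#'
#' @param start integer, first sample index (0-based, inclusive).
#' @param end integer, one past the last sample index (exclusive).
#' @return An object of class `sample_interval`: a list with elements
#'   `start` and `end`.
#' @examples
#' iv <- sample_interval(10, 20)
#' interval_length(iv)  # 10
#' @export
sample_interval <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing integers", call. = FALSE)
  if (start < 0L) stop("interval start must be >= 0", call. = FALSE)
  if (start >= end)
    stop(sprintf("invalid interval [%d, %d): start must be < end", start, end),
         call. = FALSE)
  structure(list(start = start, end = end), class = "sample_interval")
}

#' @export
print.sample_interval <- function(x, ...) {
  cat(sprintf("<sample_interval [%d, %d) length %d>\n",
              x$start, x$end, x$end - x$start))
  invisible(x)
}

#' Length of a sample interval
#' @param iv a `sample_interval`.
#' @return Integer number of samples covered.
#' @export
interval_length <- function(iv) iv$end - iv$start

# 1-based R subscript vector for a 0-based half-open interval
interval_idx <- function(iv) seq.int(iv$start + 1L, iv$end)

# coerce a data.frame row / list with start,end to sample_interval
as_interval <- function(x) {
  if (inherits(x, "sample_interval")) return(x)
  sample_interval(x$start, x$end)
}

# intervals as a data.frame(start, end); accepts list of sample_interval too
intervals_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    return(x)
  }
  if (inherits(x, "sample_interval")) x <- list(x)
  data.frame(start = vapply(x, function(i) as.integer(i$start), integer(1)),
             end = vapply(x, function(i) as.integer(i$end), integer(1)))
}

GAIT_PHASES <- c("stance", "push_off", "swing", "heel_strike")

#' Create a gait-phase label
#'
#' Associates one of the four gait phases (stance, push-off, swing,
#' heel-strike) with a sample interval.
#'
#' @param phase one of `"stance"`, `"push_off"`, `"swing"`, `"heel_strike"`.
#' @param interval a [sample_interval()].
#' @return An object of class `gait_phase_label`.
#' @export
gait_phase_label <- function(phase, interval) {
  phase <- match.arg(phase, GAIT_PHASES)
  structure(list(phase = phase, interval = as_interval(interval)),
            class = "gait_phase_label")
}

# ---------------------------------------------------------------------------
# ImuRecording
# ---------------------------------------------------------------------------

#' Construct an IMU recording
#'
#' A uniformly sampled 6-channel foot-mounted IMU stream: 3-axis
#' accelerometer plus 3-axis gyroscope, with a channel-role map assigning
#' the anatomical roles coronal (left-right), sagittal (anterior-posterior)
#' and vertical to sensor columns. Algorithms in this package address
#' channels only through roles, never through raw axis names, because device
#' mounting conventions differ between datasets.
#'
#' @param timestamps numeric vector of sample times in seconds, monotone
#'   non-decreasing, length `n >= 2`.
#' @param accel `n x 3` numeric matrix of accelerations with column names.
#' @param gyro `n x 3` numeric matrix of angular rates with column names.
#' @param channel_map named list with elements `accel` and `gyro`, each a
#'   character vector mapping the roles `coronal`, `sagittal`, `vertical`
#'   to column names of the corresponding matrix.
#' @param sample_rate_hz sampling rate; if `NULL`, inferred from timestamps.
#'   Must agree with the timestamp spacing within 1%.
#' @param units named list of unit metadata, e.g.
#'   `list(accel = "m/s^2", gyro = "deg/s")`. Units are carried as metadata
#'   and never assumed by algorithms.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(timestamps, accel, gyro, channel_map,
                          sample_rate_hz = NULL,
                          units = list(accel = "m/s^2", gyro = "deg/s")) {
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n < 2L) stop("recording must have at least 2 samples", call. = FALSE)
  d <- diff(timestamps)
  if (any(d < 0)) {
    row <- which(d < 0)[1L]
    stop(sprintf("timestamps decrease at row %d", row + 1L), call. = FALSE)
  }
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("accel/gyro must have one row per timestamp", call. = FALSE)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must each have 3 columns", call. = FALSE)
  check_channel_map(channel_map, colnames(accel), colnames(gyro))
  rate_est <- 1 / stats::median(d)
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- rate_est
  } else if (abs(sample_rate_hz - rate_est) > 0.01 * sample_rate_hz) {
    stop(sprintf(
      "declared sample rate %.3f Hz inconsistent with timestamps (%.3f Hz)",
      sample_rate_hz, rate_est), call. = FALSE)
  }
  structure(list(sample_rate_hz = sample_rate_hz, timestamps = timestamps,
                 accel = accel, gyro = gyro, channel_map = channel_map,
                 units = units),
            class = "imu_recording")
}

ROLES <- c("coronal", "sagittal", "vertical")

check_channel_map <- function(channel_map, accel_cols, gyro_cols) {
  for (sensor in c("accel", "gyro")) {
    m <- channel_map[[sensor]]
    if (is.null(m) || !all(ROLES %in% names(m)))
      stop(sprintf(
        "channel_map$%s must map all of coronal, sagittal, vertical", sensor),
        call. = FALSE)
    m <- m[ROLES]
    if (anyDuplicated(m))
      stop(sprintf("channel_map$%s maps two roles to one column", sensor),
           call. = FALSE)
    cols <- if (sensor == "accel") accel_cols else gyro_cols
    missing_cols <- setdiff(unname(m), cols)
    if (length(missing_cols))
      stop(sprintf("channel_map$%s names missing column(s): %s", sensor,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording: %d samples @ %.6g Hz (%.2f s)>\n",
              n_samples(x), x$sample_rate_hz,
              n_samples(x) / x$sample_rate_hz))
  cat(sprintf("  accel [%s] roles: %s\n", x$units$accel,
              paste(sprintf("%s=%s", ROLES, x$channel_map$accel[ROLES]),
                    collapse = " ")))
  cat(sprintf("  gyro  [%s] roles: %s\n", x$units$gyro,
              paste(sprintf("%s=%s", ROLES, x$channel_map$gyro[ROLES]),
                    collapse = " ")))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$timestamps)

#' Extract one channel of a recording by anatomical role
#'
#' @param rec an `imu_recording`.
#' @param role `"coronal"`, `"sagittal"` or `"vertical"`.
#' @param sensor `"accel"` or `"gyro"`.
#' @return Numeric vector of length `n_samples(rec)`.
#' @export
channel <- function(rec, role, sensor = c("accel", "gyro")) {
  sensor <- match.arg(sensor)
  role <- match.arg(role, ROLES)
  col <- rec$channel_map[[sensor]][[role]]
  mat <- rec[[sensor]]
  mat[, col]
}

#' Load an IMU recording from CSV
#'
#' Expects a header with a timestamp column and six sensor columns
#' (the conventional layout is `t, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`).
#'
#' @param path CSV file path.
#' @param channel_map role-to-column map as in [imu_recording()].
#' @param units unit metadata list, carried through unchanged.
#' @param time_col name of the timestamp column (default `"t"`).
#' @return A validated `imu_recording`.
#' @export
load_recording <- function(path, channel_map,
                           units = list(accel = "m/s^2", gyro = "deg/s"),
                           time_col = "t") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!time_col %in% names(df))
    stop(sprintf("missing timestamp column '%s' in %s", time_col, path),
         call. = FALSE)
  for (sensor in c("accel", "gyro")) {
    missing_roles <- setdiff(ROLES, names(channel_map[[sensor]]))
    if (length(missing_roles))
      stop(sprintf("channel_map$%s lacks role(s): %s", sensor,
                   paste(missing_roles, collapse = ", ")), call. = FALSE)
  }
  need <- unique(c(unname(channel_map$accel), unname(channel_map$gyro)))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  accel <- as.matrix(df[, unname(channel_map$accel[ROLES]), drop = FALSE])
  gyro <- as.matrix(df[, unname(channel_map$gyro[ROLES]), drop = FALSE])
  imu_recording(df[[time_col]], accel, gyro, channel_map, units = units)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [load_recording()]: writes the timestamp column plus the six
#' sensor columns under the names recorded in the channel map. Round-trips
#' values at full double precision.
#'
#' @param rec an `imu_recording`.
#' @param path output CSV path.
#' @param time_col name for the timestamp column.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, time_col = "t") {
  df <- data.frame(t = rec$timestamps, check.names = FALSE)
  names(df) <- time_col
  for (col in colnames(rec$accel)) df[[col]] <- rec$accel[, col]
  for (col in colnames(rec$gyro)) df[[col]] <- rec$gyro[, col]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Slice a recording to a sample interval
#'
#' @param rec an `imu_recording`.
#' @param iv a [sample_interval()] within `[0, n_samples(rec))`.
#' @return An `imu_recording` of length `end - start` whose sample 0 is the
#'   input's sample `start`; channel map and units are preserved.
#' @export
slice_recording <- function(rec, iv) {
  iv <- as_interval(iv)
  n <- n_samples(rec)
  if (iv$end > n)
    stop(sprintf("interval [%d, %d) out of range for %d samples",
                 iv$start, iv$end, n), call. = FALSE)
  idx <- interval_idx(iv)
  out <- rec
  out$timestamps <- rec$timestamps[idx]
  out$accel <- rec$accel[idx, , drop = FALSE]
  out$gyro <- rec$gyro[idx, , drop = FALSE]
  out
}

# ---------------------------------------------------------------------------
# AnnotationSet
# ---------------------------------------------------------------------------

#' Construct an annotation set
#'
#' Ground-truth (or predicted) stride intervals, gait-phase labels, and
#' optional per-stride reference lengths for a recording. Strides must be
#' ordered and non-overlapping; every phase interval must lie within exactly
#' one stride.
#'
#' @param strides data.frame with integer columns `start`, `end` (0-based
#'   half-open), or a list of [sample_interval()].
#' @param phases data.frame with columns `phase`, `start`, `end`, or a list
#'   of [gait_phase_label()]. May be empty.
#' @param stride_lengths optional numeric vector, one reference length per
#'   stride, in the unit declared in `meta$length_unit`.
#' @param meta named list of metadata (e.g. `length_unit`, `sample_rate_hz`).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(strides = NULL, phases = NULL,
                           stride_lengths = NULL, meta = list()) {
  strides <- if (is.null(strides) || (is.data.frame(strides) && !nrow(strides)))
    data.frame(start = integer(0), end = integer(0))
  else intervals_df(strides)
  strides$start <- as.integer(strides$start)
  strides$end <- as.integer(strides$end)
  if (nrow(strides)) {
    if (any(strides$start >= strides$end))
      stop("stride intervals must satisfy start < end", call. = FALSE)
    if (is.unsorted(strides$start))
      stop("strides must be ordered by start", call. = FALSE)
    if (nrow(strides) > 1L &&
        any(strides$start[-1L] < strides$end[-nrow(strides)]))
      stop("strides overlap", call. = FALSE)
  }
  if (is.null(phases)) {
    phases <- data.frame(phase = character(0), start = integer(0),
                         end = integer(0))
  } else if (!is.data.frame(phases)) {
    phases <- do.call(rbind, lapply(phases, function(p)
      data.frame(phase = p$phase, start = p$interval$start,
                 end = p$interval$end)))
    if (is.null(phases))
      phases <- data.frame(phase = character(0), start = integer(0),
                           end = integer(0))
  }
  phases$start <- as.integer(phases$start)
  phases$end <- as.integer(phases$end)
  if (nrow(phases)) {
    bad <- !phases$phase %in% GAIT_PHASES
    if (any(bad))
      stop(sprintf("unknown phase kind(s): %s",
                   paste(unique(phases$phase[bad]), collapse = ", ")),
           call. = FALSE)
    inside <- vapply(seq_len(nrow(phases)), function(i) {
      any(strides$start <= phases$start[i] & phases$end[i] <= strides$end)
    }, logical(1))
    if (!all(inside))
      stop("every phase interval must lie within a stride", call. = FALSE)
  }
  if (!is.null(stride_lengths)) {
    stride_lengths <- as.numeric(stride_lengths)
    if (length(stride_lengths) != nrow(strides))
      stop("stride_lengths must have one entry per stride", call. = FALSE)
  }
  structure(list(strides = strides, phases = phases,
                 stride_lengths = stride_lengths, meta = meta),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d strides, %d phase labels%s>\n",
              nrow(x$strides), nrow(x$phases),
              if (is.null(x$stride_lengths)) ""
              else sprintf(", lengths [%s]",
                           x$meta$length_unit %||% "unitless")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read annotations from JSON
#'
#' @param path JSON file written by [write_annotations()] (schema:
#'   `{strides:[{start,end}], phases:[{phase,start,end}], stride_lengths:[...],
#'   meta:{...}}`).
#' @return A validated [annotation_set()].
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  strides <- if (length(obj$strides)) as.data.frame(obj$strides)
             else NULL
  phases <- if (length(obj$phases)) as.data.frame(obj$phases) else NULL
  lengths <- if (length(obj$stride_lengths)) as.numeric(obj$stride_lengths)
             else NULL
  annotation_set(strides, phases, lengths, meta = as.list(obj$meta))
}

#' Write annotations to JSON
#'
#' Intervals are serialized as `{start, end}` integer pairs (0-based
#' half-open); the write/read round trip is lossless.
#'
#' @param ann an [annotation_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  obj <- list(
    strides = ann$strides,
    phases = ann$phases,
    stride_lengths = ann$stride_lengths,
    meta = ann$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
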