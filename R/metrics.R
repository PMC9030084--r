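# Segment-level evaluation: one-to-one interval matching, precision /
# recall / F-score, temporal intersection-over-union, RMSE, and relative
# distance error.

#' Temporal intersection-over-union of two sample intervals
#'
#' Intersection is the overlap length (0 when disjoint). The union is the
#' spanning interval `max(end) - min(start)`, which coincides with the true
#' set union whenever the intervals overlap; for disjoint intervals the span
#' includes the gap, making the ratio 0 anyway since the intersection is
#' empty.
#'
#' @param a,b [sample_interval()] objects (or anything with `start`, `end`).
#' @return A number in `[0, 1]`.
#' @export
interval_iou <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  inter <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  if (inter == 0L) return(0)
  span <- max(a$end, b$end) - min(a$start, b$start)
  inter / span
}

#' Match predicted segments to labeled segments one-to-one
#'
#' Greedy matching by descending IoU: each predicted and each labeled
#' interval joins at most one pair, a pair counts as a true positive iff its
#' IoU reaches `min_iou` (with `min_iou = 0`, any overlap counts). Unmatched
#' predictions are false positives, unmatched labels false negatives.
#'
#' @param predicted,labeled data.frames with `start`, `end` columns (0-based
#'   half-open), or lists of [sample_interval()].
#' @param min_iou minimum IoU for a pair to count as a true positive.
#' @return An object of class `match_result`: list with counts `tp`, `fp`,
#'   `fn`, a data.frame `pairs` (`pred`, `label` row indices and `iou`), and
#'   the `min_iou` used.
#' @export
match_segments <- function(predicted, labeled, min_iou = 0) {
  P <- intervals_df(predicted); L <- intervals_df(labeled)
  np <- nrow(P); nl <- nrow(L)
  pairs <- data.frame(pred = integer(0), label = integer(0),
                      iou = numeric(0))
  if (np && nl) {
    iou_mat <- outer(seq_len(np), seq_len(nl), Vectorize(function(i, j) {
      interval_iou(sample_interval(P$start[i], P$end[i]),
                   sample_interval(L$start[j], L$end[j]))
    }))
    repeat {
      best <- which.max(iou_mat)
      val <- iou_mat[best]
      if (!length(val) || val <= 0 || val < min_iou) break
      i <- (best - 1L) %% np + 1L
      j <- (best - 1L) %/% np + 1L
      pairs <- rbind(pairs, data.frame(pred = i, label = j, iou = val))
      iou_mat[i, ] <- -Inf
      iou_mat[, j] <- -Inf
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = nl - tp, pairs = pairs,
                 min_iou = min_iou),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP %d, FP %d, FN %d (min IoU %.3g)>\n",
              x$tp, x$fp, x$fn, x$min_iou))
  invisible(x)
}

#' Precision, recall and F-score from match counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and the F-score
#' is their harmonic mean. With `tp = 0` all three are 0 by convention.
#'
#' @param tp,fp,fn non-negative counts, or a [match_segments()] result as
#'   first argument.
#' @return Named numeric vector `precision`, `recall`, `f_score`.
#' @export
f_score <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) {
    fp <- tp$fp; fn <- tp$fn; tp <- tp$tp
  }
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp == 0) return(c(precision = 0, recall = 0, f_score = 0))
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  c(precision = p, recall = r, f_score = 2 * p * r / (p + r))
}

#' Root-mean-square error of stride-length predictions
#'
#' @param y_ref reference lengths.
#' @param y_pred predicted lengths, same length and unit as `y_ref`.
#' @return RMSE in the reference unit.
#' @export
rmse <- function(y_ref, y_pred) {
  if (length(y_ref) != length(y_pred))
    stop("y_ref and y_pred must have equal length", call. = FALSE)
  if (!length(y_ref)) stop("need at least one stride", call. = FALSE)
  sqrt(mean((y_ref - y_pred)^2))
}

#' Relative error of the accumulated walked distance
#'
#' `RE = (distance - sum(y_pred)) / distance * 100`, comparing the
#' accumulated stride-length estimates against an independently measured
#' path distance.
#'
#' @param distance true path distance (> 0), same unit as the predictions.
#' @param y_pred per-stride length predictions.
#' @return Relative error in percent (signed).
#' @export
relative_error <- function(distance, y_pred) {
  if (!is.finite(distance) || distance <= 0)
    stop("distance must be a positive number", call. = FALSE)
  (distance - sum(y_pred)) / distance * 100
}

#' Evaluate predicted gait phases against ground truth
#'
#' Per phase kind: one-to-one segment matching, precision/recall/F-score,
#' and the mean IoU over the matched (true positive) pairs.
#'
#' @param predicted,truth data.frames with columns `phase`, `start`, `end`,
#'   or [annotation_set()] objects (their `phases` are used).
#' @param min_iou matching threshold passed to [match_segments()].
#' @return Data.frame with one row per phase kind: `phase`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f_score`, `mean_iou`.
#' @export
evaluate_phases <- function(predicted, truth, min_iou = 0) {
  pred <- if (inherits(predicted, "annotation_set")) predicted$phases
          else predicted
  lab <- if (inherits(truth, "annotation_set")) truth$phases else truth
  rows <- lapply(GAIT_PHASES, function(ph) {
    p <- pred[pred$phase == ph, c("start", "end"), drop = FALSE]
    l <- lab[lab$phase == ph, c("start", "end"), drop = FALSE]
    m <- match_segments(p, l, min_iou)
    fs <- f_score(m)
    data.frame(phase = ph, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = fs[["precision"]], recall = fs[["recall"]],
               f_score = fs[["f_score"]],
               mean_iou = if (m$tp) mean(m$pairs$iou) else NA_real_)
  })
  do.call(rbind, rows)
}
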