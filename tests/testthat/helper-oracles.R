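# Independent oracles used to verify the implementation.

# Brute-force open-begin-open-end DTW: for every start column, run a plain
# textbook DTW (steps {(1,1),(1,0),(0,1)}, horizontal accumulation allowed
# in the first row) and take the minimum accumulated distance over all
# (start, end) pairs. Written with naive loops, independent of the package's
# dynamic-programming code.
brute_force_subdtw_min <- function(cost) {
  L <- nrow(cost)
  n <- ncol(cost)
  best <- Inf
  for (s in seq_len(n)) {
    width <- n - s + 1L
    D <- matrix(Inf, L, width)
    D[1, 1] <- cost[1, s]
    for (i in seq_len(width)[-1]) D[1, i] <- D[1, i - 1] + cost[1, s + i - 1]
    for (j in seq_len(L)[-1]) {
      D[j, 1] <- D[j - 1, 1] + cost[j, s]
      for (i in seq_len(width)[-1]) {
        D[j, i] <- cost[j, s + i - 1] +
          min(D[j - 1, i - 1], D[j - 1, i], D[j, i - 1])
      }
    }
    best <- min(best, min(D[L, ]))
  }
  best
}

# Exhaustive contiguous bipartition of sorted 1-D points minimizing the
# within-cluster sum of squares (both parts non-empty).
wcss_bipartition <- function(points) {
  points <- sort(points)
  k <- length(points)
  wcss <- function(x) if (length(x) <= 1L) 0 else sum((x - mean(x))^2)
  best <- NULL
  best_val <- Inf
  for (cut in seq_len(k - 1L)) {
    left <- points[seq_len(cut)]
    right <- points[seq.int(cut + 1L, k)]
    val <- wcss(left) + wcss(right)
    if (val < best_val) {
      best_val <- val
      best <- list(left = left, right = right)
    }
  }
  best
}

# integer-grid interval overlap oracle: intersection by sample enumeration,
# union as the spanning extent
grid_iou <- function(a, b) {
  sa <- seq.int(a[1], a[2] - 1L)
  sb <- seq.int(b[1], b[2] - 1L)
  inter <- length(intersect(sa, sb))
  if (inter == 0L) return(0)
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}
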