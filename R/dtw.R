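#' Squared-difference local cost
#'
#' The pointwise cost used throughout the package: `d(x, y) = (x - y)^2`.
#' All DTW distances here are sums of these squared costs; no final square
#' root is taken, so distances are in units of squared signal amplitude.
#'
#' @param x,y Finite numeric scalars.
#' @return A nonnegative scalar, `(x - y)^2`.
#' @examples
#' local_cost(2.5, 3)  # 0.25
#' @export
local_cost <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y)) {
    abort_input("`x` and `y` must be finite numeric scalars")
  }
  (x - y)^2
}

#' Dynamic time warping distance
#'
#' Unconstrained DTW between two series of possibly different lengths,
#' computed by dynamic programming over the accumulated cost matrix.  The
#' distance is the minimum, over all boundary-anchored monotone-continuous
#' warping paths, of the summed squared pointwise differences.  Note that
#' the value is a sum of squared costs with no square root: `dtw_distance`
#' of two series differing by a constant c at k aligned points is `k * c^2`.
#'
#' @param a,b Numeric vectors (finite, length >= 1).
#' @return Nonnegative scalar distance (squared-amplitude units).
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 3))  # 0
#' dtw_distance(c(0, 0), 1)              # 2: both zeros align to the 1
#' @seealso [dtw_path()] for the optimal alignment, [dtw_pairwise()] for a
#'   cached distance look-up table.
#' @export
dtw_distance <- function(a, b) {
  a <- check_series(a, "a")
  b <- check_series(b, "b")
  cpp_dtw_distance(a, b)
}

#' Optimal warping path
#'
#' Backtracks the accumulated cost matrix to recover one optimal alignment.
#' The path is a two-column integer matrix of 1-based index pairs starting
#' at `(1, 1)` and ending at `(length(a), length(b))`; successive rows
#' differ by `(1, 1)`, `(1, 0)` or `(0, 1)`.  When several predecessors of a
#' cell tie, the diagonal step is preferred, then the step advancing `a`,
#' then the step advancing `b`; this makes paths (and everything built on
#' them, notably DBA) deterministic.
#'
#' @inheritParams dtw_distance
#' @return A list with elements `path` (L x 2 integer matrix) and
#'   `distance` (same value as [dtw_distance()]).
#' @examples
#' dtw_path(c(0, 0), 1)$path  # rbind(c(1, 1), c(2, 1))
#' @export
dtw_path <- function(a, b) {
  a <- check_series(a, "a")
  b <- check_series(b, "b")
  cpp_dtw_path(a, b)
}

#' Pairwise DTW distance look-up table
#'
#' Computes all pairwise DTW distances of a set of series once, so the
#' self-training loop can read distances from the table instead of
#' recomputing them at every iteration.  The result is symmetric with a
#' zero diagonal.
#'
#' @param series A non-empty list of numeric vectors.
#' @return An `n x n` symmetric numeric matrix of DTW distances.
#' @examples
#' dtw_pairwise(list(c(0, 0), 1, c(1, 1)))
#' @export
dtw_pairwise <- function(series) {
  series <- check_series_list(series, "series")
  cpp_dtw_pairwise(series)
}

#' Z-normalize a series
#'
#' Subtracts the mean and divides by the (sample) standard deviation.  A
#' constant series maps to all zeros.  Normalization is an opt-in
#' preprocessing step at the I/O layer; the DTW core never normalizes.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
znorm <- function(x) {
  x <- check_series(x, "x")
  s <- stats::sd(x)
  if (length(x) == 1L || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}
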