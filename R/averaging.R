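# Time-series averaging: DBA under DTW and the pointwise Euclidean baseline.

#' One DBA refinement step
#'
#' Aligns the current barycenter with every series in the set (barycenter
#' first in the DTW alignment, diagonal-first tie-breaks), pools per
#' barycenter position the series elements paired with it, and replaces
#' each position by the arithmetic mean of its pooled set.  The barycenter
#' length never changes.
#'
#' @param current Numeric vector, the current barycenter.
#' @param series_set Non-empty list of numeric vectors.
#' @return Numeric vector of the same length as `current`.
#' @examples
#' dba_iteration(c(0, 0), list(c(2, 2), c(4, 4)))  # c(3, 3)
#' dba_iteration(5, list(c(1, 3)))                 # 2
#' @export
dba_iteration <- function(current, series_set) {
  current <- check_series(current, "current")
  series_set <- check_series_list(series_set)
  cpp_dba_iteration(current, series_set)
}

#' DTW barycenter average (DBA)
#'
#' Computes the average sequence of a set of (possibly unequal-length)
#' series under DTW.  The initial barycenter is a member of the set drawn
#' uniformly at random with `seed`; it is then refined by exactly
#' `iterations` calls to [dba_iteration()].  The barycenter keeps the
#' length of its initializer throughout.  The whole computation is
#' deterministic given the inputs and the seed.
#'
#' The number of refinement iterations defaults to 15, the setting used for
#' all barycenter-guided labeling runs in this package.
#'
#' @param series_set Non-empty list of numeric vectors.
#' @param iterations Positive integer number of refinement steps.
#' @param seed Integer seed for the random choice of initializer.
#' @param init Optional integer index into `series_set` overriding the
#'   random initializer (used mainly for testing).
#' @return Numeric vector: the barycenter.  Attributes `init_index` and
#'   `iterations` record the initializer and the number of steps run.
#' @examples
#' dba_average(list(c(0, 0, 0), c(2, 2, 2)), iterations = 15, seed = 1)
#' @export
dba_average <- function(series_set, iterations = 15L, seed = 1L, init = NULL) {
  series_set <- check_series_list(series_set)
  iterations <- as.integer(iterations)
  if (length(iterations) != 1L || is.na(iterations) || iterations < 1L) {
    abort_input("`iterations` must be a positive integer")
  }
  n <- length(series_set)
  if (is.null(init)) {
    init <- withr::with_seed(as.integer(seed), sample.int(n, 1L))
  } else {
    init <- as.integer(init)
    if (init < 1L || init > n) abort_input("`init` out of range")
  }
  center <- series_set[[init]]
  for (i in seq_len(iterations)) {
    center <- cpp_dba_iteration(center, series_set)
  }
  attr(center, "init_index") <- init
  attr(center, "iterations") <- iterations
  center
}

#' Pointwise Euclidean average
#'
#' Position-wise arithmetic mean of a set of equal-length series.  This is
#' the averaging rule of the Euclidean-center labeling variant; it is
#' undefined for unequal lengths, which raise an error.
#'
#' @param series_set Non-empty list of equal-length numeric vectors.
#' @return Numeric vector of column means.
#' @examples
#' euclidean_average(list(c(1, 1), c(1, 3), c(4, 2)))  # c(2, 2)
#' @export
euclidean_average <- function(series_set) {
  series_set <- check_series_list(series_set)
  lens <- lengths(series_set)
  if (length(unique(lens)) != 1L) {
    abort_input("euclidean_average requires equal-length series")
  }
  colMeans(do.call(rbind, series_set))
}

#' DBA objective: total DTW distance to a center
#'
#' The quantity DBA descends: the sum over the set of DTW distances from
#' each series to the barycenter.  Non-increasing across [dba_iteration()]
#' refinements.
#'
#' @param center Numeric vector.
#' @param series_set Non-empty list of numeric vectors.
#' @return Nonnegative scalar.
#' @export
dba_objective <- function(center, series_set) {
  center <- check_series(center, "center")
  series_set <- check_series_list(series_set)
  sum(cpp_dtw_to_many(center, series_set))
}
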