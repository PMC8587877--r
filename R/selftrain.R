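# Positive-unlabeled self-training: the 1NN scheme, the barycenter-guided
# scheme, the SCC stopping rule, and the final positive/negative cut.

#' Construct a positive-unlabeled dataset
#'
#' Bundles the seed positive-labeled set `PL`, the unlabeled pool `U`, and
#' (optionally) the hidden ground-truth labels of `U`, which are used only
#' for evaluation and never by the labeling algorithms.
#'
#' @param PL Non-empty list of numeric vectors: the seed positives.
#' @param U Non-empty list of numeric vectors: the unlabeled pool.
#' @param truth Optional integer/logical vector, one entry per element of
#'   `U`, with 1/TRUE marking hidden positives.
#' @return An object of class `pu_dataset`.
#' @seealso [make_pu_split()] to build one from a labeled dataset.
#' @export
pu_dataset <- function(PL, U, truth = NULL) {
  PL <- check_series_list(PL, "PL")
  U <- check_series_list(U, "U")
  if (!is.null(truth)) {
    truth <- as.integer(truth)
    if (length(truth) != length(U) || anyNA(truth) || !all(truth %in% 0:1)) {
      abort_input("`truth` must be a 0/1 vector with one entry per element of U")
    }
  }
  structure(list(PL = PL, U = U, truth = truth), class = "pu_dataset")
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat(sprintf("<pu_dataset> |PL| = %d, |U| = %d%s\n",
              length(x$PL), length(x$U),
              if (is.null(x$truth)) "" else
                sprintf(" (%d hidden positives)", sum(x$truth))))
  invisible(x)
}

new_trace <- function(order, info) {
  structure(list(order = as.integer(order), info = as.numeric(info)),
            class = "labeling_trace")
}

#' @export
print.labeling_trace <- function(x, ...) {
  cat(sprintf("<labeling_trace> %d iterations; info range [%g, %g]\n",
              length(x$order), min(x$info), max(x$info)))
  invisible(x)
}

# Pairwise distance table over c(PL, U), computed if not supplied.
resolve_distances <- function(data, distances) {
  n <- length(data$PL) + length(data$U)
  if (is.null(distances)) {
    return(cpp_dtw_pairwise(c(data$PL, data$U)))
  }
  if (!is.matrix(distances) || nrow(distances) != n || ncol(distances) != n) {
    abort_config(sprintf(
      "`distances` must be a %d x %d matrix covering PL followed by U", n, n))
  }
  if (anyNA(distances)) abort_config("`distances` has missing entries")
  distances
}

#' Rank the unlabeled pool by 1NN self-training
#'
#' The classic self-training loop: at each iteration the unlabeled series
#' whose minimum DTW distance to the current labeled set is smallest is
#' labeled, its `info` value (that minimum distance) is recorded, and it
#' joins the labeled set.  The loop runs until the pool is empty, producing
#' a complete labeling order; the positive/negative cut is decided
#' afterwards by [scc()].  Ties are broken toward the lowest original index
#' in `U`.
#'
#' @param data A [pu_dataset()].
#' @param distances Optional precomputed [dtw_pairwise()] matrix over
#'   `c(PL, U)` (rows/cols: PL first, then U in order).  Computed if
#'   missing.
#' @return A `labeling_trace`: `order` (indices into `U` in labeling order,
#'   a permutation of `seq_along(U)`) and `info` (the recorded minimum
#'   distances).
#' @export
st_rank <- function(data, distances = NULL) {
  stopifnot(inherits(data, "pu_dataset"))
  D <- resolve_distances(data, distances)
  m <- length(data$PL)
  u <- length(data$U)
  remaining <- seq_len(u)               # original U indices, ascending
  # current min distance from each remaining pool member to the labeled set
  mind <- apply(D[m + remaining, seq_len(m), drop = FALSE], 1L, min)
  order <- integer(u)
  info <- numeric(u)
  for (t in seq_len(u)) {
    k <- which.min(mind)                # first minimum = lowest original index
    order[t] <- remaining[k]
    info[t] <- mind[k]
    newcol <- D[m + remaining, m + remaining[k], drop = TRUE]
    mind <- pmin(mind, newcol)[-k]
    remaining <- remaining[-k]
  }
  new_trace(order, info)
}

#' Rank the unlabeled pool by barycenter-guided self-training
#'
#' The barycenter-guided variant: at each iteration the average sequence of
#' the current labeled set is recomputed (DBA under DTW, or the pointwise
#' Euclidean mean), and the unlabeled series closest in DTW distance to
#' that center is labeled next.  The recorded `info` value is, by default,
#' still the minimum DTW distance from the selected series to the labeled
#' set (not to the center), so the stopping rule sees the same statistic
#' as 1NN self-training; set `info = "center"` for the center-distance
#' variant.
#'
#' Each iteration's random DBA initializer uses a sub-seed derived from
#' `seed` and the iteration counter via [derive_seed()], so a whole run is
#' reproducible from one master seed.
#'
#' @inheritParams st_rank
#' @param averager `"dba"` or `"euclidean"`.
#' @param dba_iterations Positive integer, DBA refinement steps (default 15).
#' @param seed Integer master seed for the DBA initializers.
#' @param info `"pl"` (default) records the minimum distance to the labeled
#'   set; `"center"` records the distance to the center.
#' @return A `labeling_trace`, as for [st_rank()].
#' @export
st_average_rank <- function(data, averager = c("dba", "euclidean"),
                            dba_iterations = 15L, seed = 1L,
                            distances = NULL, info = c("pl", "center")) {
  stopifnot(inherits(data, "pu_dataset"))
  averager <- match.arg(averager)
  info <- match.arg(info)
  D <- resolve_distances(data, distances)
  m <- length(data$PL)
  u <- length(data$U)
  labeled_idx <- seq_len(m)             # columns of D currently labeled
  labeled_set <- data$PL
  remaining <- seq_len(u)
  order <- integer(u)
  infov <- numeric(u)
  for (t in seq_len(u)) {
    center <- if (averager == "dba") {
      dba_average(labeled_set, iterations = dba_iterations,
                  seed = derive_seed(seed, t))
    } else {
      euclidean_average(labeled_set)
    }
    dc <- cpp_dtw_to_many(center, data$U[remaining])
    k <- which.min(dc)
    sel <- remaining[k]
    order[t] <- sel
    infov[t] <- if (info == "pl") {
      min(D[m + sel, labeled_idx])
    } else {
      dc[k]
    }
    labeled_set <- c(labeled_set, data$U[sel])
    labeled_idx <- c(labeled_idx, m + sel)
    remaining <- remaining[-k]
  }
  new_trace(order, infov)
}

#' Stopping-criterion confidence (SCC)
#'
#' Locates the positive/negative cut in a labeling trace.  For iterations
#' `i` in `[2, u]`,
#' \deqn{SCC(i) = \frac{|info(i) - info(i-1)|}{Std(info(1..i))} \times
#'       \frac{u - (i - 1)}{u},}
#' where `u` is the initial pool size.  The stop index is the argmax of
#' SCC minus 1 (the default) or minus 2 (`stop_rule = "minus2"`, the
#' original rule of the criterion's source method).  Iteration 1 has no
#' predecessor and is excluded.  Degenerate ratios are defined as
#' `0/0 := 0` and `positive/0 := Inf` (such an iteration wins the argmax);
#' argmax ties go to the smallest `i`.
#'
#' @param info Numeric vector of recorded minimum distances, one per
#'   labeling iteration.
#' @param u_size Initial pool size; must equal `length(info)`.
#' @param std `"sample"` (denominator n-1, the default) or `"population"`.
#' @param stop_rule `"minus1"` (default) or `"minus2"`.
#' @return An object of class `scc_result`: `scc` (per-iteration values,
#'   `NA` at i = 1), `argmax`, and `stop`.
#' @examples
#' scc(c(1, 1, 1, 9))$stop  # 3
#' @export
scc <- function(info, u_size = length(info), std = c("sample", "population"),
                stop_rule = c("minus1", "minus2")) {
  std <- match.arg(std)
  stop_rule <- match.arg(stop_rule)
  info <- as.numeric(info)
  if (anyNA(info)) abort_input("`info` contains missing values")
  u <- as.integer(u_size)
  if (u < 2L) abort_input("SCC needs a pool of at least 2 series")
  if (length(info) != u) abort_input("`info` must have length `u_size`")
  sdev <- function(x) {
    if (std == "sample") stats::sd(x) else pop_sd(x)
  }
  vals <- rep(NA_real_, u)
  for (i in 2:u) {
    num <- abs(info[i] - info[i - 1L])
    s <- sdev(info[1:i])
    shrink <- (u - (i - 1L)) / u
    vals[i] <- if (s == 0) {
      if (num == 0) 0 else Inf
    } else {
      num / s * shrink
    }
  }
  argmax <- 1L + which.max(vals[2:u])   # first maximum = smallest i
  stop_idx <- argmax - switch(stop_rule, minus1 = 1L, minus2 = 2L)
  structure(list(scc = vals, argmax = argmax, stop = stop_idx),
            class = "scc_result")
}

#' Cut a labeling trace into positive and negative sets
#'
#' The first `stop` series in labeling order, together with the original
#' seed positives, form the positive set; the remaining series form the
#' negative set.  The two sets always partition the seed set plus the pool
#' exactly.
#'
#' @param trace A `labeling_trace` from [st_rank()] or [st_average_rank()].
#' @param stop Integer in `[0, |U|]`.
#' @param data The [pu_dataset()] the trace was computed on.
#' @return A list of class `labeling_result`: `positive` and `negative`
#'   (lists of series), plus `positive_idx` / `negative_idx` (indices into
#'   `U`) and `stop`.
#' @export
finalize_labels <- function(trace, stop, data) {
  stopifnot(inherits(trace, "labeling_trace"), inherits(data, "pu_dataset"))
  u <- length(trace$order)
  stop <- as.integer(stop)
  if (length(stop) != 1L || is.na(stop) || stop < 0L || stop > u) {
    abort_input(sprintf("`stop` must lie in [0, %d]", u))
  }
  pos_u <- trace$order[seq_len(stop)]
  neg_u <- if (stop < u) trace$order[(stop + 1L):u] else integer(0)
  structure(list(positive = c(data$PL, data$U[pos_u]),
                 negative = data$U[neg_u],
                 positive_idx = pos_u,
                 negative_idx = neg_u,
                 stop = stop),
            class = "labeling_result")
}

#' Run a complete positive-unlabeled labeling pipeline
#'
#' Ranks the pool with the chosen method, applies the SCC stopping rule,
#' and cuts the trace.  Methods: `"st-scc"` (1NN self-training),
#' `"scc-center-dtw"` (barycenter-guided, DBA center), `"scc-center-ed"`
#' (barycenter-guided, pointwise Euclidean center).  All three use DTW as
#' the series distance and SCC as the stopping rule.
#'
#' @inheritParams st_average_rank
#' @param method One of `"st-scc"`, `"scc-center-dtw"`, `"scc-center-ed"`.
#' @param stop_rule,std Passed to [scc()].
#' @return A list of class `pu_labeling`: `trace`, `scc`, `stop`, `result`
#'   (a `labeling_result`), and `method`.
#' @export
pu_label <- function(data, method = c("st-scc", "scc-center-dtw", "scc-center-ed"),
                     dba_iterations = 15L, seed = 1L,
                     stop_rule = c("minus1", "minus2"),
                     std = c("sample", "population"),
                     distances = NULL, info = c("pl", "center")) {
  method <- match.arg(method)
  stop_rule <- match.arg(stop_rule)
  std <- match.arg(std)
  info <- match.arg(info)
  D <- resolve_distances(data, distances)
  trace <- switch(method,
    "st-scc" = st_rank(data, distances = D),
    "scc-center-dtw" = st_average_rank(data, "dba",
                                       dba_iterations = dba_iterations,
                                       seed = seed, distances = D, info = info),
    "scc-center-ed" = st_average_rank(data, "euclidean",
                                      seed = seed, distances = D, info = info))
  sc <- scc(trace$info, length(data$U), std = std, stop_rule = stop_rule)
  res <- finalize_labels(trace, sc$stop, data)
  structure(list(trace = trace, scc = sc, stop = sc$stop, result = res,
                 method = method),
            class = "pu_labeling")
}

#' @export
print.pu_labeling <- function(x, ...) {
  cat(sprintf("<pu_labeling> method = %s; stop = %d; |positive| = %d, |negative| = %d\n",
              x$method, x$stop, length(x$result$positive),
              length(x$result$negative)))
  invisible(x)
}

#' Theoretical slowdown of barycenter-guided self-training
#'
#' With DBA recomputed at every labeling iteration, the barycenter-guided
#' loop costs a factor `I + 1` more DTW work than the look-up-table 1NN
#' loop, where `I` is the number of DBA refinement iterations: the DBA
#' recomputations contribute `I` full passes and the candidate scan one
#' more.
#'
#' @param dba_iterations Positive integer `I`.
#' @return `dba_iterations + 1`.
#' @examples
#' theoretical_speedup(15)  # 16
#' @export
theoretical_speedup <- function(dba_iterations = 15L) {
  dba_iterations <- as.integer(dba_iterations)
  if (length(dba_iterations) != 1L || is.na(dba_iterations) ||
      dba_iterations < 1L) {
    abort_input("`dba_iterations` must be a positive integer")
  }
  dba_iterations + 1L
}
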