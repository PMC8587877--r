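# Independent oracles used to cross-check the dynamic-programming DTW.

# Brute-force DTW: minimum summed squared cost over all boundary-anchored
# monotone-continuous warping paths, found by plain recursion over the
# three admissible moves with no memoization -- an exhaustive enumeration
# of every path, independent of the accumulated-cost-matrix recurrence.
oracle_dtw_bruteforce <- function(a, b) {
  m <- length(a)
  n <- length(b)
  rec <- function(i, j) {
    cost <- (a[i] - b[j])^2
    if (i == m && j == n) {
      return(cost)
    }
    best <- Inf
    if (i < m && j < n) best <- min(best, rec(i + 1, j + 1))
    if (i < m) best <- min(best, rec(i + 1, j))
    if (j < n) best <- min(best, rec(i, j + 1))
    cost + best
  }
  rec(1, 1)
}

# Memoized top-down recursion (suffix costs), for pairs too long to
# enumerate exhaustively.  Shares no code with the package's bottom-up DP.
oracle_dtw_memo <- function(a, b) {
  m <- length(a)
  n <- length(b)
  memo <- matrix(NA_real_, m, n)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) {
      return(memo[i, j])
    }
    cost <- (a[i] - b[j])^2
    tail <- if (i == m && j == n) {
      0
    } else {
      best <- Inf
      if (i < m && j < n) best <- min(best, rec(i + 1, j + 1))
      if (i < m) best <- min(best, rec(i + 1, j))
      if (j < n) best <- min(best, rec(i, j + 1))
      best
    }
    memo[i, j] <<- cost + tail
    memo[i, j]
  }
  rec(1, 1)
}

# All integer series of the given lengths over an alphabet, as a list.
all_integer_series <- function(lengths, alphabet = 0:2) {
  out <- list()
  for (len in lengths) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ])))
  }
  out
}

random_integer_series <- function(max_len = 5L, alphabet = 0:2) {
  len <- sample.int(max_len, 1L)
  as.numeric(sample(alphabet, len, replace = TRUE))
}

# Cache-free 1NN self-training reference: recomputes every DTW distance
# with dtw_distance() at the moment it is needed, never touching a
# pairwise table.
reference_st_rank <- function(data) {
  labeled <- data$PL
  pool <- data$U
  remaining <- seq_along(pool)
  order <- integer(0)
  info <- numeric(0)
  while (length(remaining) > 0L) {
    mind <- vapply(remaining, function(j) {
      min(vapply(labeled, function(x) dtw_distance(pool[[j]], x), numeric(1)))
    }, numeric(1))
    k <- which.min(mind)
    order <- c(order, remaining[k])
    info <- c(info, mind[k])
    labeled <- c(labeled, pool[remaining[k]])
    remaining <- remaining[-k]
  }
  list(order = order, info = info)
}

sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_series_set <- function(n_min = 3L, n_max = 6L, len_min = 8L,
                              len_max = 15L) {
  n <- sample_range(n_min, n_max)
  lapply(seq_len(n), function(i) rnorm(sample_range(len_min, len_max)))
}
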