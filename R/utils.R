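# Internal helpers: input validation, error classes, seed plumbing.

abort_input <- function(msg) {
  stop(errorCondition(msg, class = c("putsc_input_error", "putsc_error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("putsc_config_error", "putsc_error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("putsc_data_error", "putsc_error")))
}

# A time series is a plain numeric vector: length >= 1, all values finite.
check_series <- function(x, arg = "series") {
  if (is.matrix(x) || is.list(x) || !is.numeric(x)) {
    abort_input(sprintf("`%s` must be a numeric vector", arg))
  }
  if (length(x) < 1L) {
    abort_input(sprintf("`%s` must have length >= 1", arg))
  }
  if (!all(is.finite(x))) {
    abort_input(sprintf("`%s` contains non-finite values", arg))
  }
  as.numeric(x)
}

check_series_list <- function(xs, arg = "series_set") {
  if (!is.list(xs) || length(xs) < 1L) {
    abort_input(sprintf("`%s` must be a non-empty list of numeric vectors", arg))
  }
  lapply(seq_along(xs), function(i) {
    check_series(xs[[i]], sprintf("%s[[%d]]", arg, i))
  })
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Repeated stochastic steps inside one run (for instance the random DBA
#' initializer drawn at every self-training iteration) each need their own
#' seed while the whole run stays reproducible from a single master seed.
#' The derivation is a small multiplicative-congruential fold of the master
#' seed with one or more integer counters; the result always lies in
#' `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param ... Integer counters (iteration number, repetition number, ...).
#' @return A single integer seed.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 1, 3)
#' @export
derive_seed <- function(seed, ...) {
  p <- 2147483629  # largest prime below 2^31
  s <- as.double(seed) %% p
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% p
  }
  as.integer(s)
}

# Population (denominator N) standard deviation.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
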