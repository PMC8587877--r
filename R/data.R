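# UCR-format I/O, PU-split construction, and seeded synthetic generators.

#' Construct a labeled time-series dataset
#'
#' @param series List of numeric vectors.
#' @param labels Integer class labels, one per series.
#' @param name Dataset name.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(series, labels, name = "dataset") {
  series <- check_series_list(series, "series")
  labels <- as.integer(labels)
  if (length(labels) != length(series) || anyNA(labels)) {
    abort_input("`labels` must be one integer per series")
  }
  structure(list(series = series, labels = labels, name = as.character(name)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s: %d series, %d classes, lengths %d..%d\n",
              x$name, length(x$series), length(unique(x$labels)),
              min(lengths(x$series)), max(lengths(x$series))))
  invisible(x)
}

detect_sep <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t"
  else if (grepl(",", line, fixed = TRUE)) ","
  else "[[:space:]]+"
}

#' Read a UCR-style delimited time-series file
#'
#' Each line holds an integer class label followed by the series values,
#' separated by tabs or commas (auto-detected from the first line; plain
#' whitespace also accepted).  Trailing empty fields -- the usual encoding
#' of variable-length series -- are dropped.  Line order is preserved.
#'
#' @param path Path to the file.
#' @param name Dataset name; defaults to the file name without extension.
#' @param normalize If `TRUE`, z-normalize every series with [znorm()]
#'   after reading (off by default; many UCR datasets ship pre-normalized).
#' @return A [labeled_dataset()].
#' @export
read_ucr <- function(path, name = NULL, normalize = FALSE) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_data(sprintf("empty dataset file: %s", path))
  sep <- detect_sep(lines[[1L]])
  fields <- strsplit(lines, sep)
  labels <- integer(length(fields))
  series <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    # drop trailing empty fields (variable-length rows)
    while (length(f) > 1L && !nzchar(trimws(f[length(f)]))) {
      f <- f[-length(f)]
    }
    lab <- suppressWarnings(as.numeric(f[[1L]]))
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (is.na(lab) || lab != round(lab)) {
      abort_data(sprintf("line %d: non-integer class label '%s'", i, f[[1L]]))
    }
    if (length(vals) == 0L || anyNA(vals)) {
      abort_data(sprintf("line %d: non-numeric or missing series values", i))
    }
    labels[i] <- as.integer(lab)
    series[[i]] <- if (normalize) znorm(vals) else vals
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  labeled_dataset(series, labels, name)
}

#' Write a dataset in UCR delimited format
#'
#' @param ds A [labeled_dataset()].
#' @param path Output path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_ucr <- function(ds, path, sep = "\t") {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (!sep %in% c("\t", ",")) abort_config("`sep` must be tab or comma")
  lines <- vapply(seq_along(ds$series), function(i) {
    paste(c(ds$labels[i], format(ds$series[[i]], digits = 17, trim = TRUE,
                                 scientific = FALSE)),
          collapse = sep)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a positive-unlabeled split from a labeled dataset
#'
#' Draws `pl_size` instances of the positive class uniformly without
#' replacement as the seed set `PL`; every remaining instance (positive or
#' negative) goes into the unlabeled pool `U`, whose true binary labels are
#' kept aside for evaluation only.  With `include`, specific instances
#' (indices into the dataset) are forced into `PL` and only the remainder
#' is drawn at random -- used, for example, to seed `PL` from instances
#' adjacent to the class boundary.
#'
#' @param ds A [labeled_dataset()].
#' @param positive_label Integer label treated as positive (default 1).
#' @param pl_size Number of seed positives (default 3).
#' @param seed Integer seed for the draw.
#' @param include Optional indices (into `ds$series`) of positives that
#'   must be part of `PL`.
#' @return A [pu_dataset()] with extra fields `pl_idx` and `u_idx` giving
#'   the original dataset indices of `PL` and `U`.
#' @export
make_pu_split <- function(ds, positive_label = 1L, pl_size = 3L, seed = 1L,
                          include = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  pl_size <- as.integer(pl_size)
  if (pl_size < 1L) abort_config("`pl_size` must be >= 1")
  if (length(unique(ds$labels)) < 2L) {
    abort_data("dataset needs at least two distinct labels for a PU split")
  }
  pos_idx <- which(ds$labels == positive_label)
  if (length(pos_idx) < pl_size) {
    abort_config(sprintf("only %d instances of label %d; pl_size = %d",
                         length(pos_idx), positive_label, pl_size))
  }
  include <- as.integer(include)
  if (length(include) > 0L) {
    if (!all(include %in% pos_idx)) {
      abort_config("`include` must index positive instances")
    }
    if (length(include) > pl_size) abort_config("`include` longer than pl_size")
  }
  pool <- setdiff(pos_idx, include)
  n_draw <- pl_size - length(include)
  drawn <- if (n_draw > 0L) {
    withr::with_seed(as.integer(seed), pool[sample.int(length(pool), n_draw)])
  } else {
    integer(0)
  }
  pl_idx <- sort(c(include, drawn))
  u_idx <- setdiff(seq_along(ds$series), pl_idx)
  out <- pu_dataset(PL = ds$series[pl_idx],
                    U = ds$series[u_idx],
                    truth = as.integer(ds$labels[u_idx] == positive_label))
  out$pl_idx <- pl_idx
  out$u_idx <- u_idx
  out
}

#' Generate a cylinder-bell-funnel dataset
#'
#' The classic three-class simulated benchmark: on `t = 1..length`, a
#' plateau event starts at an onset `a` drawn uniformly from integers
#' `[16, 32]` and lasts `b - a` drawn uniformly from `[32, 96]`, with
#' height `6 + eta`, `eta ~ N(0, amp_sd)`.  Cylinders hold the plateau
#' flat, bells ramp linearly up across `[a, b]`, funnels ramp linearly
#' down; standard-normal noise (`noise_sd`) is added everywhere.  Labels:
#' 1 = cylinder, 2 = bell, 3 = funnel.  Setting `amp_sd = 0` and
#' `noise_sd = 0` yields the noiseless shapes (handy in tests).
#'
#' @param n_per_class Series per class.
#' @param length Series length (default 128; must be >= 32 so the onset
#'   and duration ranges fit).
#' @param seed Integer seed.
#' @param noise_sd,amp_sd Noise and amplitude-jitter standard deviations
#'   (both default 1, the standard formulation).
#' @return A [labeled_dataset()].
#' @export
generate_cbf <- function(n_per_class, length = 128L, seed = 1L,
                         noise_sd = 1, amp_sd = 1) {
  length <- as.integer(length)
  if (length < 32L) abort_config("`length` must be >= 32")
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) abort_config("`n_per_class` must be >= 1")
  withr::with_seed(as.integer(seed), {
    t <- seq_len(length)
    one <- function(shape) {
      a <- sample(16:32, 1L)
      b <- a + sample(32:96, 1L)
      b <- min(b, length)
      amp <- 6 + rnorm(1L, sd = amp_sd)
      on <- t >= a & t <= b
      base <- switch(shape,
        cylinder = amp * on,
        bell = amp * on * (t - a) / (b - a),
        funnel = amp * on * (b - t) / (b - a))
      base + rnorm(length, sd = noise_sd)
    }
    shapes <- rep(c("cylinder", "bell", "funnel"), each = n_per_class)
    series <- lapply(shapes, one)
    labels <- rep(1:3, each = n_per_class)
    labeled_dataset(series, labels, "cbf")
  })
}

#' Generate a boundary-seeded two-class scenario
#'
#' A controlled fixture for the failure mode that motivates
#' barycenter-guided self-training: seed positives that sit near the
#' class boundary drag 1NN self-training into the negative class, while
#' the labeled set's average stays representative of the positive class.
#'
#' Every series is a Gaussian bump `A * exp(-(t - c)^2 / (2 * 5^2))` plus
#' noise, with the bump center jittered a few steps around mid-series (a
#' temporal shift DTW absorbs).  Class structure lives in the amplitude
#' `A`: interior positives sit on a jittered regular grid starting at 8.5
#' with unit spacing (so each one's nearest same-class neighbour is about
#' one amplitude unit away), negatives draw `A ~ U(3, 5.9)` (dense: their
#' nearest-neighbour spacing is a fraction of a unit), and a designated
#' fraction of positives ("boundary" positives) sit between the classes at
#' `A = 6 + 2.5 * (1 - overlap) + U(0, 0.1)`.  At `overlap = 0` the
#' boundary positives merge with the interior grid and the classes are far
#' apart; as `overlap` approaches 1 they move within a whisker of the
#' strongest negatives -- closer to the negative class than any unlabeled
#' interior positive is to the labeled set -- so a boundary-seeded 1NN
#' chain leaks into the dense negative amplitudes before it reaches the
#' interior positives.
#'
#' @param n_pos,n_neg Class sizes (each >= 3).
#' @param overlap In `[0, 1]`: how close boundary positives sit to the
#'   negative class.
#' @param seed Integer seed.
#' @param length Series length (default 60).
#' @param noise_sd Additive noise standard deviation (default 0.1).
#' @param boundary_frac Fraction of positives generated at the boundary
#'   (default 1/8, at least one).
#' @return A [labeled_dataset()] (positive label 1, negative label 2) with
#'   attribute `boundary_idx`: the dataset indices of the boundary
#'   positives.
#' @seealso [boundary_pu_split()] to seed `PL` from a boundary instance.
#' @export
generate_boundary_scenario <- function(n_pos = 8L, n_neg = 12L, overlap = 0.9,
                                       seed = 1L, length = 60L,
                                       noise_sd = 0.1, boundary_frac = 1 / 8) {
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  if (n_pos < 3L || n_neg < 3L) abort_config("class counts must be >= 3")
  if (overlap < 0 || overlap > 1) abort_config("`overlap` must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    t <- seq_len(as.integer(length))
    mid <- length / 2
    bump <- function(amp) {
      c0 <- mid + sample(-3:3, 1L)
      amp * exp(-(t - c0)^2 / (2 * 25)) + rnorm(length, sd = noise_sd)
    }
    n_b <- max(1L, round(boundary_frac * n_pos))
    n_int <- n_pos - n_b
    amps_pos <- c(6 + 2.5 * (1 - overlap) + runif(n_b, 0, 0.1),       # boundary
                  8.5 + seq_len(n_int) - 1 + runif(n_int, -0.15, 0.15))  # interior
    amps_neg <- runif(n_neg, 3, 5.9)
    series <- c(lapply(amps_pos, bump), lapply(amps_neg, bump))
    labels <- c(rep(1L, n_pos), rep(2L, n_neg))
    ds <- labeled_dataset(series, labels, "boundary_scenario")
    attr(ds, "boundary_idx") <- seq_len(n_b)
    ds
  })
}

#' PU split seeded from a class-boundary instance
#'
#' Builds a [make_pu_split()] whose `PL` contains one boundary positive
#' (drawn at random among the generator-marked boundary instances) plus
#' `pl_size - 1` interior positives -- the configuration in which plain
#' 1NN self-training is most easily dragged across the class boundary.
#'
#' @param ds A dataset from [generate_boundary_scenario()].
#' @param pl_size Seed set size (default 3).
#' @param seed Integer seed.
#' @return A [pu_dataset()].
#' @export
boundary_pu_split <- function(ds, pl_size = 3L, seed = 1L) {
  b_idx <- attr(ds, "boundary_idx")
  if (is.null(b_idx)) {
    abort_config("dataset has no `boundary_idx` attribute; use generate_boundary_scenario()")
  }
  pick <- withr::with_seed(as.integer(seed),
                           b_idx[sample.int(length(b_idx), 1L)])
  interior <- setdiff(which(ds$labels == 1L), b_idx)
  if (length(interior) < pl_size - 1L) {
    abort_config("not enough interior positives for the requested pl_size")
  }
  others <- withr::with_seed(derive_seed(seed, 1L),
                             interior[sample.int(length(interior),
                                                 pl_size - 1L)])
  split <- make_pu_split(ds, positive_label = 1L, pl_size = pl_size,
                         seed = seed, include = c(pick, others))
  split
}
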