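# Scoring (F1), tie-averaged ranking, and the repeated-random-initialization
# experiment harness.

#' F1 score from confusion counts
#'
#' Precision is correct positive predictions over positive predictions,
#' recall is correct positive predictions over positive instances, and F1
#' is their harmonic mean `2pr / (p + r)`.  Conventions: with no positive
#' predictions, `p := 0`; with no positive instances, `r := 0`; when
#' `p + r = 0`, `F1 := 0`.
#'
#' @param correct_positive Number of correct positive predictions.
#' @param predicted_positive Total number of positive predictions.
#' @param actual_positive Number of true positive instances.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(8, 10, 16)  # p = 0.8, r = 0.5 -> 8/13
#' @export
f1_score <- function(correct_positive, predicted_positive, actual_positive) {
  cp <- as.numeric(correct_positive)
  pp <- as.numeric(predicted_positive)
  ap <- as.numeric(actual_positive)
  if (anyNA(c(cp, pp, ap)) || any(c(cp, pp, ap) < 0)) {
    abort_input("confusion counts must be nonnegative")
  }
  if (cp > min(pp, ap)) {
    abort_input("correct positives cannot exceed predictions or instances")
  }
  p <- if (pp == 0) 0 else cp / pp
  r <- if (ap == 0) 0 else cp / ap
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Score a labeling against the hidden truth of the pool
#'
#' Evaluation covers the unlabeled pool only: the seeded positives are
#' excluded from the confusion counts.
#'
#' @param labeling A `pu_labeling` (from [pu_label()]) or a
#'   `labeling_result` (from [finalize_labels()]).
#' @param data The [pu_dataset()] that was labeled; must carry `truth`.
#' @return A list with `precision`, `recall`, `f1`, and the three
#'   underlying counts.
#' @export
score_labeling <- function(labeling, data) {
  stopifnot(inherits(data, "pu_dataset"))
  if (is.null(data$truth)) abort_input("`data` has no ground-truth labels")
  res <- if (inherits(labeling, "pu_labeling")) labeling$result else labeling
  stopifnot(inherits(res, "labeling_result"))
  pred_pos <- res$positive_idx
  cp <- sum(data$truth[pred_pos] == 1L)
  pp <- length(pred_pos)
  ap <- sum(data$truth == 1L)
  p <- if (pp == 0) 0 else cp / pp
  r <- if (ap == 0) 0 else cp / ap
  list(precision = p, recall = r, f1 = f1_score(cp, pp, ap),
       correct_positive = cp, predicted_positive = pp, actual_positive = ap)
}

#' Tie-averaged competition ranks
#'
#' The best score receives rank 1; tied scores share the arithmetic mean
#' of the positions they would jointly occupy (two methods tied for first
#' both get `(1 + 2) / 2 = 1.5`).
#'
#' @param scores Numeric vector, one score per method.
#' @param higher_is_better If `TRUE` (default), larger scores rank better.
#' @return Numeric vector of ranks; for `k` methods the ranks always sum
#'   to `k (k + 1) / 2`.
#' @examples
#' tie_average_ranks(c(0.9, 0.5, 0.7))  # 1 3 2
#' @export
tie_average_ranks <- function(scores, higher_is_better = TRUE) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) abort_input("`scores` must be non-empty")
  if (higher_is_better) scores <- -scores
  rank(scores, ties.method = "average")
}

#' Aggregate a dataset-by-method rank grid
#'
#' Mean and population (denominator N) standard deviation of each method's
#' ranks across datasets -- the "average ranking" summary of a benchmark
#' table.
#'
#' @param rank_matrix Numeric matrix, datasets in rows, methods in columns
#'   (column names = method names).
#' @return A data frame with columns `method`, `mean_rank`, `sd_rank`.
#' @export
summarize_ranks <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  if (is.null(colnames(rank_matrix))) {
    colnames(rank_matrix) <- paste0("method", seq_len(ncol(rank_matrix)))
  }
  data.frame(method = colnames(rank_matrix),
             mean_rank = colMeans(rank_matrix),
             sd_rank = apply(rank_matrix, 2L, pop_sd),
             row.names = NULL)
}

dba_based <- function(method) method == "scc-center-dtw"

#' Repeated-random-initialization labeling experiment
#'
#' Runs the full label-then-stop pipeline for each method over
#' `n_pl_draws` random seed-positive draws, scoring F1 on the pool against
#' the hidden truth.  Methods whose barycenter has a random initializer
#' (`"scc-center-dtw"`) are additionally repeated `n_dba_reps` times per
#' draw; deterministic methods run once per draw.  With the defaults (20
#' draws, 20 repetitions) a DBA-based method is summarized over 400 runs
#' and the others over 20.  The pairwise DTW table is computed once per
#' draw and shared by all methods.  Fully deterministic given `seed`.
#'
#' @param ds A [labeled_dataset()].
#' @param methods Character vector of method names (see [pu_label()]).
#' @param positive_label Label treated as positive (default 1).
#' @param pl_size Seed set size (default 3).
#' @param dba_iterations DBA refinement steps (default 15).
#' @param n_pl_draws Number of random seed draws (default 20).
#' @param n_dba_reps Repetitions per draw for DBA-based methods
#'   (default 20).
#' @param seed Master seed.
#' @param stop_rule,std Passed to [scc()].
#' @return A data frame with one row per method: `dataset`, `method`,
#'   `mean_f1`, `std_f1` (sample standard deviation over runs), `runs`,
#'   `rank` (tie-averaged across methods by mean F1).
#' @export
run_experiment <- function(ds, methods = c("st-scc", "scc-center-dtw",
                                           "scc-center-ed"),
                           positive_label = 1L, pl_size = 3L,
                           dba_iterations = 15L, n_pl_draws = 20L,
                           n_dba_reps = 20L, seed = 1L,
                           stop_rule = "minus1", std = "sample") {
  stopifnot(inherits(ds, "labeled_dataset"))
  methods <- match.arg(methods, c("st-scc", "scc-center-dtw", "scc-center-ed"),
                       several.ok = TRUE)
  f1s <- stats::setNames(rep(list(numeric(0)), length(methods)), methods)
  for (d in seq_len(n_pl_draws)) {
    split <- make_pu_split(ds, positive_label = positive_label,
                           pl_size = pl_size, seed = derive_seed(seed, d))
    D <- dtw_pairwise(c(split$PL, split$U))
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      reps <- if (dba_based(m)) as.integer(n_dba_reps) else 1L
      for (r in seq_len(reps)) {
        fit <- pu_label(split, method = m, dba_iterations = dba_iterations,
                        seed = derive_seed(seed, d, mi, r), distances = D,
                        stop_rule = stop_rule, std = std)
        f1s[[m]] <- c(f1s[[m]], score_labeling(fit, split)$f1)
      }
    }
  }
  means <- vapply(f1s, mean, numeric(1))
  sds <- vapply(f1s, function(x) if (length(x) > 1L) stats::sd(x) else 0,
                numeric(1))
  out <- data.frame(dataset = ds$name,
                    method = methods,
                    mean_f1 = unname(means),
                    std_f1 = unname(sds),
                    runs = unname(vapply(f1s, length, integer(1))),
                    row.names = NULL)
  out$rank <- if (length(methods) > 1L) tie_average_ranks(out$mean_f1) else NA_real_
  out
}

#' Boundary-seeded comparison of 1NN and barycenter-guided self-training
#'
#' The package's headline property as a measurable experiment: on the
#' boundary-seeded two-class scenario, with the seed set containing one
#' boundary positive, barycenter-guided labeling should beat plain 1NN
#' self-training in mean F1.  For each of `n_seeds` replicates a fresh
#' scenario and split are generated and every method is scored once.
#'
#' @param n_seeds Number of replicates (default 20).
#' @param overlap,n_pos,n_neg Scenario parameters; see
#'   [generate_boundary_scenario()].
#' @param pl_size Seed set size (default 3).
#' @param dba_iterations DBA refinement steps (default 15).
#' @param seed Master seed.
#' @param methods Methods to compare.
#' @return A data frame with columns `replicate`, `method`, `f1`, `stop`.
#' @export
compare_boundary_methods <- function(n_seeds = 20L, overlap = 0.9,
                                     n_pos = 8L, n_neg = 12L, pl_size = 3L,
                                     dba_iterations = 15L, seed = 1L,
                                     methods = c("st-scc", "scc-center-dtw")) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    ds <- generate_boundary_scenario(n_pos = n_pos, n_neg = n_neg,
                                     overlap = overlap,
                                     seed = derive_seed(seed, i))
    split <- boundary_pu_split(ds, pl_size = pl_size,
                               seed = derive_seed(seed, i, 2L))
    D <- dtw_pairwise(c(split$PL, split$U))
    for (m in methods) {
      fit <- pu_label(split, method = m, dba_iterations = dba_iterations,
                      seed = derive_seed(seed, i, 3L), distances = D)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = i, method = m,
                   f1 = score_labeling(fit, split)$f1, stop = fit$stop)
    }
  }
  do.call(rbind, rows)
}
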