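test_that("1NN self-training selects nearest-to-labeled first and records info", {
  d <- pu_dataset(PL = list(c(0, 0)), U = list(c(10, 10), c(1, 1)))
  tr <- st_rank(d)
  expect_identical(tr$order, c(2L, 1L))
  # after (1,1) joins the labeled set, (10,10) is nearest to it: 2 * 81
  expect_equal(tr$info, c(2, 162))

  d1 <- pu_dataset(PL = list(c(0, 1)), U = list(c(5, 5)))
  tr1 <- st_rank(d1)
  expect_identical(length(tr1$order), 1L)
  expect_equal(tr1$info, dtw_distance(c(5, 5), c(0, 1)))
})

test_that("every ranking is a permutation of the pool", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      d <- pu_dataset(PL = random_series_set(2, 3),
                      U = random_series_set(4, 8))
      tr <- st_rank(d)
      expect_setequal(tr$order, seq_along(d$U))
      tra <- st_average_rank(d, "dba", dba_iterations = 2, seed = rep)
      expect_setequal(tra$order, seq_along(d$U))
    }
  })
})

test_that("ranking through the pairwise look-up table equals cache-free recomputation", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      d <- pu_dataset(PL = random_series_set(1, 3, 5, 8),
                      U = random_series_set(4, 7, 5, 8))
      tr <- st_rank(d, distances = dtw_pairwise(c(d$PL, d$U)))
      ref <- reference_st_rank(d)
      expect_identical(tr$order, as.integer(ref$order))
      expect_equal(tr$info, ref$info)
    }
  })
})

test_that("barycenter-guided ranking selects nearest-to-center, info stays nearest-to-labeled", {
  d <- pu_dataset(PL = list(c(0, 0), c(4, 4)), U = list(c(10, 10), c(1, 1)))
  tr <- st_average_rank(d, "euclidean")
  # center (2,2): DTW 2 to (1,1) vs 128 to (10,10)
  expect_identical(tr$order, c(2L, 1L))
  expect_equal(tr$info[1], 2)  # min distance of (1,1) to PL, not to the center
  trc <- st_average_rank(d, "euclidean", info = "center")
  expect_equal(trc$info[1], dtw_distance(c(1, 1), c(2, 2)))

  d1 <- pu_dataset(PL = list(c(1, 5)), U = list(c(0, 2)))
  expect_identical(length(st_average_rank(d1, "dba", seed = 4)$order), 1L)
})

test_that("with a single seed positive the first selections of both schemes coincide", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      d <- pu_dataset(PL = random_series_set(1, 1), U = random_series_set(4, 6))
      t_nn <- st_rank(d)
      t_avg <- st_average_rank(d, "dba", dba_iterations = 1, seed = rep)
      expect_identical(t_avg$order[1], t_nn$order[1])
    }
  })
})

test_that("identical seed positives make both schemes fully coincide", {
  s <- c(1, 0, 2, 4)
  d <- pu_dataset(PL = rep(list(s), 3),
                  U = list(c(1, 0, 2, 5), c(9, 9, 9, 9), c(0, 0, 1, 3)))
  t_nn <- st_rank(d)
  t_avg <- st_average_rank(d, "dba", seed = 8)
  expect_identical(t_avg$order[1], t_nn$order[1])
})

test_that("SCC normalizes jumps and applies the degenerate-ratio rules", {
  # prefixes of equal values have zero Std: 0/0 := 0; at i = 4 the sample
  # Std of (1,1,1,9) is 4, so SCC(4) = (8 / 4) * (1 / 4) = 0.5
  r <- scc(c(1, 1, 1, 9))
  expect_equal(r$scc, c(NA, 0, 0, 0.5))
  expect_identical(r$argmax, 4L)
  expect_identical(r$stop, 3L)
  expect_identical(scc(c(1, 1, 1, 9), stop_rule = "minus2")$stop, 2L)

  # population-Std flavor: Std(1,1,1,9) = sqrt(12)
  rp <- scc(c(1, 1, 1, 9), std = "population")
  expect_equal(rp$scc[4], 8 / sqrt(12) / 4)

  # strictly constant info: every SCC is 0, argmax ties to i = 2
  rc <- scc(rep(3.5, 6))
  expect_true(all(rc$scc[-1] == 0))
  expect_identical(rc$stop, 1L)

  # a jump after a flat prefix dominates later, already-normalized jumps
  ri <- scc(c(2, 2, 7, 9))
  expect_equal(ri$scc[3], 5 / sd(c(2, 2, 7)) * (2 / 4))
  expect_identical(ri$stop, 2L)

  expect_error(scc(5), class = "putsc_input_error")
})

test_that("the default stop index always lies in [1, u - 1]", {
  withr::with_seed(29, {
    for (rep in 1:30) {
      u <- sample(2:15, 1)
      r <- scc(runif(u))
      expect_gte(r$stop, 1L)
      expect_lte(r$stop, u - 1L)
    }
  })
})

test_that("finalize cuts the trace at the stop index", {
  d <- pu_dataset(PL = random_series_set(3, 3), U = random_series_set(5, 5))
  tr <- st_rank(d)
  u <- length(d$U)
  all_cut <- finalize_labels(tr, u, d)
  expect_identical(length(all_cut$negative), 0L)
  none <- finalize_labels(tr, 0, d)
  expect_identical(length(none$positive), length(d$PL))
  expect_error(finalize_labels(tr, u + 1, d), class = "putsc_input_error")
})

test_that("finalize always partitions the seed set and pool exactly", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      p <- sample(1:3, 1)
      u <- sample(2:10, 1)
      d <- pu_dataset(PL = random_series_set(p, p, 4, 6),
                      U = random_series_set(u, u, 4, 6))
      trace <- structure(list(order = sample.int(length(d$U)),
                              info = runif(length(d$U))),
                         class = "labeling_trace")
      stop <- sample(0:length(d$U), 1)
      res <- finalize_labels(trace, stop, d)
      expect_identical(length(res$positive) + length(res$negative),
                       length(d$PL) + length(d$U))
      expect_identical(sort(c(res$positive_idx, res$negative_idx)),
                       seq_along(d$U))
      expect_identical(length(res$negative), length(d$U) - stop)
    }
  })
})

test_that("pu_label runs the full pipeline deterministically", {
  ds <- generate_boundary_scenario(seed = 400)
  sp <- boundary_pu_split(ds, seed = 401)
  a <- pu_label(sp, "scc-center-dtw", seed = 77)
  b <- pu_label(sp, "scc-center-dtw", seed = 77)
  expect_identical(a$trace$order, b$trace$order)
  expect_identical(a$stop, b$stop)
  expect_error(pu_label(sp, "no-such-method"))
})

test_that("the barycenter recomputation slowdown is one more than the iteration count", {
  expect_identical(theoretical_speedup(15), 16L)
  expect_identical(theoretical_speedup(1), 2L)
  expect_error(theoretical_speedup(0), class = "putsc_input_error")
})
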