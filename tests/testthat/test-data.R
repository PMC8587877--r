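test_that("UCR reader parses labels and values in both dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("1,0.0,1.0,2.0", f)
  ds <- read_ucr(f)
  expect_identical(ds$labels, 1L)
  expect_equal(ds$series[[1]], c(0, 1, 2))

  writeLines(c("2\t0.5\t-1.5", "1\t3\t4"), f)
  ds <- read_ucr(f)
  expect_identical(ds$labels, c(2L, 1L))  # line order preserved
  expect_equal(ds$series[[2]], c(3, 4))
})

test_that("trailing empty fields are dropped; malformed rows are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1,0.5,0.7,,", "2,1,2,3,4"), f)
  ds <- read_ucr(f)
  expect_equal(lengths(ds$series), c(2L, 4L))

  writeLines("1,0.5,oops,0.7", f)
  expect_error(read_ucr(f), class = "putsc_data_error")
  writeLines("x,0.5,0.7", f)
  expect_error(read_ucr(f), class = "putsc_data_error")
  writeLines(character(0), f)
  expect_error(read_ucr(f), class = "putsc_data_error")
  expect_error(read_ucr(file.path(tempdir(), "no-such-file.txt")),
               class = "putsc_data_error")
})

test_that("write-then-read round-trips a dataset exactly", {
  withr::with_seed(8, {
    ds <- labeled_dataset(lapply(1:6, function(i) rnorm(sample(3:7, 1))),
                          labels = rep(1:2, 3), name = "rt")
  })
  for (sep in c("\t", ",")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_ucr(ds, f, sep = sep)
    back <- read_ucr(f, name = "rt")
    expect_identical(back$labels, ds$labels)
    expect_equal(back$series, ds$series)
  }
})

test_that("a CBF-sized file yields the expected records", {
  ds <- generate_cbf(10, length = 128, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ucr(ds, f)
  back <- read_ucr(f)
  expect_identical(length(back$series), 30L)
  expect_identical(sort(unique(back$labels)), 1:3)
  expect_true(all(lengths(back$series) == 128L))
})

test_that("PU splits draw seeded positives and keep everything else in the pool", {
  ds <- generate_boundary_scenario(n_pos = 5, n_neg = 7, seed = 6)
  sp <- make_pu_split(ds, pl_size = 3, seed = 10)
  expect_identical(length(sp$PL), 3L)
  expect_identical(length(sp$PL) + length(sp$U), length(ds$series))
  expect_identical(sum(sp$truth), 2L)  # 5 positives minus 3 seeds
  expect_identical(make_pu_split(ds, pl_size = 3, seed = 10)$u_idx, sp$u_idx)

  # seeding every positive leaves only negatives in the pool
  sp_all <- make_pu_split(ds, pl_size = 5, seed = 2)
  expect_identical(sum(sp_all$truth), 0L)

  expect_error(make_pu_split(ds, pl_size = 6), class = "putsc_config_error")
  expect_error(make_pu_split(ds, include = which(ds$labels == 2L)[1]),
               class = "putsc_config_error")
})

test_that("cylinder-bell-funnel generator matches the noiseless shapes", {
  ds <- generate_cbf(2, length = 64, seed = 5, noise_sd = 0, amp_sd = 0)
  expect_identical(length(ds$series), 6L)
  cyl <- ds$series[[1]]
  on <- which(cyl != 0)
  expect_true(all(cyl[on] == 6))            # flat plateau at height 6
  expect_identical(on, min(on):max(on))     # single contiguous event
  expect_gte(min(on), 16L)
  bell <- ds$series[[3]]
  ramp <- bell[bell != 0]
  expect_true(all(diff(ramp) > 0))          # linear ramp up
  funnel <- ds$series[[5]]
  expect_true(all(diff(funnel[funnel != 0]) < 0))
  expect_identical(generate_cbf(3, seed = 4)$series,
                   generate_cbf(3, seed = 4)$series)
})

test_that("boundary scenario is seeded, marked, and separable at zero overlap", {
  ds <- generate_boundary_scenario(seed = 14)
  expect_identical(ds$series, generate_boundary_scenario(seed = 14)$series)
  b <- attr(ds, "boundary_idx")
  expect_true(length(b) >= 1L && all(ds$labels[b] == 1L))

  # separable limit: the labeling order is positives-first, so the cut at
  # the true positive count is perfect for either scheme
  ds0 <- generate_boundary_scenario(overlap = 0, seed = 15)
  sp <- boundary_pu_split(ds0, seed = 16)
  for (m in c("st-scc", "scc-center-dtw")) {
    fit <- pu_label(sp, m, seed = 17)
    cut <- finalize_labels(fit$trace, sum(sp$truth), sp)
    expect_identical(score_labeling(cut, sp)$f1, 1)
  }
})

test_that("boundary seeding misleads 1NN but not barycenter-guided selection", {
  n_seeds <- 20
  neg_first_nn <- 0
  pos_first_avg <- 0
  for (i in seq_len(n_seeds)) {
    ds <- generate_boundary_scenario(seed = derive_seed(2024, i))
    sp <- boundary_pu_split(ds, seed = derive_seed(2024, i, 2))
    D <- dtw_pairwise(c(sp$PL, sp$U))
    t_nn <- st_rank(sp, distances = D)
    t_avg <- st_average_rank(sp, "dba", seed = derive_seed(2024, i, 3),
                             distances = D)
    neg_first_nn <- neg_first_nn + (sp$truth[t_nn$order[1]] == 0L)
    pos_first_avg <- pos_first_avg + (sp$truth[t_avg$order[1]] == 1L)
  }
  expect_gte(neg_first_nn, n_seeds / 2)
  expect_gte(pos_first_avg, n_seeds / 2)
})
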