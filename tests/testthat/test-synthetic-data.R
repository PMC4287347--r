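test_that("zero-noise planted group rows are identical with Pearson 1", {
  d <- two_task_design(8, list(three_pair_group(1, amplitude = 1)),
                       noise_sd = 0, seed = 11)
  gen <- generate_edge_level(d)
  rows <- which(gen$group_of_edge == 1)
  expect_length(rows, 3)
  w <- gen$ets$weights[rows, ]
  expect_equal(w[1, ], w[2, ])
  expect_equal(w[1, ], w[3, ])
  expect_equal(cor(w[1, ], w[2, ]), 1)
})

test_that("amplitude 0 gives independent noise with vanishing correlations", {
  d <- planted_design(6,
                      tasks = data.frame(task = "a", tr = 2, n_windows = 400),
                      groups = list(three_pair_group(1, amplitude = 0)),
                      noise_sd = 0.3, seed = 21)
  gen <- generate_edge_level(d)
  cc <- cor(t(gen$ets$weights))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("within-group correlation exceeds between-group correlation", {
  d <- planted_design(8,
                      tasks = data.frame(task = "a", tr = 2, n_windows = 40),
                      groups = list(three_pair_group(1, amplitude = 0.9)),
                      noise_sd = 0.3, seed = 7)
  gen <- generate_edge_level(d)
  cc <- cor(t(gen$ets$weights))
  members <- which(gen$group_of_edge == 1)
  others <- which(gen$group_of_edge == 0)
  within <- cc[members, members][upper.tri(diag(3))]
  between <- cc[members, others]
  expect_gt(mean(within), mean(between))
})

test_that("edge-level generation is deterministic given the seed", {
  d <- two_task_design(8, list(three_pair_group(1, 0.8)), 0.2, seed = 5)
  expect_identical(generate_edge_level(d), generate_edge_level(d))
})

test_that("invalid designs are rejected", {
  tasks <- data.frame(task = "a", tr = 2, n_windows = 8)
  expect_error(planted_group(rbind(c(1, 2)), amplitude = 1.4), "amplitude")
  expect_error(planted_group(rbind(c(3, 3)), amplitude = 1), "distinct")
  expect_error(
    planted_design(4, tasks, list(planted_group(rbind(c(1, 9)), 0.5))),
    "outside")
  expect_error(
    planted_design(6, tasks, list(planted_group(rbind(c(1, 2)), 0.5),
                                  planted_group(rbind(c(2, 1)), 0.5))),
    "share")
  expect_error(
    planted_design(4, data.frame(task = "a", tr = 2, n_windows = 1), list()))
})

test_that("region-level planting drives the pair's windowed edge weight", {
  # amplitude 1, zero noise: the planted pair's edge weight is ~1 in every
  # active window; the task-restricted variant is ~1 only inside its task
  d <- planted_design(6,
                      tasks = data.frame(task = c("rest", "word"),
                                         tr = c(2, 2.5), n_windows = c(6, 6)),
                      groups = list(planted_group(rbind(c(1, 2)), 1,
                                                  task = "rest")),
                      noise_sd = 0, seed = 2)
  sim <- generate_region_level(d)
  ets <- suppressWarnings(edge_ts_from_runs(sim$runs, band = NULL))
  e <- pair_to_edge(1, 2, 6)
  rest_cols <- which(ets$window_tasks == "rest")
  expect_true(all(ets$weights[e, rest_cols] > 0.99))
})

test_that("task-restricted region-level groups show elevated within-task edge-edge correlation", {
  d <- planted_design(8,
                      tasks = data.frame(task = c("rest", "word"),
                                         tr = c(2, 2), n_windows = c(10, 10)),
                      groups = list(three_pair_group(1, 0.9, task = "word")),
                      noise_sd = 0.2, seed = 9)
  sim <- generate_region_level(d)
  ets <- edge_ts_from_runs(sim$runs, band = NULL)
  members <- which(sim$group_of_edge == 1)
  stat_word <- within_task_statistic(members, ets, "word")
  stat_rest <- within_task_statistic(members, ets, "rest")
  expect_gt(stat_word, stat_rest + 0.1)
  expect_gt(stat_word, 0.2)
})

test_that("region-level generation is deterministic and carriers pass the band filter", {
  d <- planted_design(5,
                      tasks = data.frame(task = "rest", tr = 2, n_windows = 4),
                      groups = list(planted_group(rbind(c(1, 2)), 0.8)),
                      noise_sd = 0.2, seed = 4)
  s1 <- generate_region_level(d)
  s2 <- generate_region_level(d)
  expect_identical(s1, s2)
  # band-pass filtering keeps most of the carrier energy
  run <- s1$runs[[1]]
  filtered <- bandpass(run)
  interior <- 30:(ncol(run$data) - 30)
  ratio <- sd(filtered$data[3, interior]) / sd(run$data[3, interior])
  expect_gt(ratio, 0.7)
})

test_that("simulated FD traces hit the requested mean and the exclusion rule", {
  expect_identical(generate_fd_trace(50, 0), numeric(50))
  tr <- generate_fd_trace(100, 0.3, seed = 1)
  expect_true(all(tr >= 0))
  expect_gt(mean(tr), 0.285)
  expect_lt(mean(tr), 0.315)
  # mean 0.2 survives the 0.25 mm rule; mean 0.3 does not
  mk <- function(m) region_run(matrix(rnorm(303), 3), 2, "rest", "s1",
                               fd = generate_fd_trace(100, m, seed = 2))
  qc <- exclude_high_motion(list(mk(0.2), mk(0.3)))
  expect_length(qc$kept, 1)
  expect_equal(qc$excluded, "s1/rest")
  expect_error(generate_fd_trace(0, 0.1))
})

test_that("region-size tables plant detectable outliers deterministically", {
  t1 <- generate_region_size_table(8, 5, outlier_spec = list(high_cv = 3,
                                                             cv = 0.5),
                                   seed = 3)
  expect_identical(t1, generate_region_size_table(8, 5,
                                                  outlier_spec = list(high_cv = 3, cv = 0.5),
                                                  seed = 3))
  expect_true(all(t1$voxels >= 1))
  fine <- t1[t1$scale == "fine", ]
  cvs <- sapply(split(fine$voxels, fine$region), coefficient_of_variation)
  flagged <- names(cvs)[cvs > 0.30]
  expect_true(unique(fine$region)[3] %in% flagged)
  # unremarkable regions stay below the 30% rule
  expect_lt(median(cvs), 0.30)
  # fine regions carry parent pointers into the coarse scale
  expect_true(all(fine$parent %in% t1$region[t1$scale == "coarse"]))
})
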