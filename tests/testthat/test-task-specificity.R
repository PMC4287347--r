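task_ets <- function(weights, n_nodes, tasks_per_block, block) {
  edge_ts(weights, n_nodes, rep(tasks_per_block, each = block))
}

test_that("within-task statistic is the mean pairwise member correlation", {
  set.seed(2)
  w <- matrix(runif(6 * 12, -0.5, 0.5), 6, 12)
  w[2, ] <- w[1, ]  # identical members within every task
  ets <- task_ets(w, 4, c("a", "b"), 6)
  expect_equal(within_task_statistic(c(1, 2), ets, "a"), 1)
  # three members over 6 task windows: brute-force mean of the 3 Pearsons
  members <- c(1, 3, 5)
  cols <- 7:12
  expected <- mean(c(naive_pearson(w[1, cols], w[3, cols]),
                     naive_pearson(w[1, cols], w[5, cols]),
                     naive_pearson(w[3, cols], w[5, cols])))
  expect_equal(within_task_statistic(members, ets, "b"), expected,
               tolerance = 1e-12)
  expect_error(within_task_statistic(members, ets, "zz"), "at least 4")
})

test_that("independent member edges have near-zero statistic", {
  set.seed(3)
  w <- matrix(rnorm(6 * 400), 6, 400)
  w <- w / max(abs(w))
  ets <- task_ets(w, 4, c("a", "b"), 200)
  expect_lt(abs(within_task_statistic(1:3, ets, "a")), 0.15)
})

test_that("permutation test flags planted task restriction and respects its contract", {
  d <- planted_design(10,
                      tasks = data.frame(task = c("rest", "word"),
                                         tr = c(2, 2), n_windows = c(12, 12)),
                      groups = list(three_pair_group(1, 0.9, task = "word")),
                      noise_sd = 0.2, seed = 6)
  gen <- generate_edge_level(d)
  members <- which(gen$group_of_edge == 1)
  word <- task_permutation_test(members, gen$ets, "word",
                                n_permutations = 500, seed = 1)
  rest <- task_permutation_test(members, gen$ets, "rest",
                                n_permutations = 500, seed = 1)
  expect_lt(word$p, 0.01)
  expect_gt(rest$p, 0.10)
  # p is bounded away from zero and deterministic under the seed
  expect_gte(word$p, 1 / 501)
  expect_identical(word,
                   task_permutation_test(members, gen$ets, "word",
                                         n_permutations = 500, seed = 1))
  expect_error(task_permutation_test(members, gen$ets, "word",
                                     n_permutations = 0), "n_permutations")
})

test_that("p-values are invariant to relabeling within the non-target pool", {
  d <- planted_design(8,
                      tasks = data.frame(task = c("a", "b", "c"),
                                         tr = c(2, 2, 2),
                                         n_windows = c(8, 8, 8)),
                      groups = list(three_pair_group(1, 0.9, task = "a")),
                      noise_sd = 0.2, seed = 12)
  gen <- generate_edge_level(d)
  members <- which(gen$group_of_edge == 1)
  p1 <- task_permutation_test(members, gen$ets, "a", 300, seed = 4)$p
  # swap the b and c labels: the pooled non-target window set is unchanged
  relabeled <- gen$ets
  relabeled$window_tasks[relabeled$window_tasks == "b"] <- "tmp"
  relabeled$window_tasks[relabeled$window_tasks == "c"] <- "b"
  relabeled$window_tasks[relabeled$window_tasks == "tmp"] <- "c"
  p2 <- task_permutation_test(members, relabeled, "a", 300, seed = 4)$p
  expect_identical(p1, p2)
})

test_that("stationary co-evolution is not labeled task-specific", {
  d <- planted_design(10,
                      tasks = data.frame(task = c("a", "b", "c"),
                                         tr = c(2, 2, 2),
                                         n_windows = c(10, 10, 10)),
                      groups = list(three_pair_group(1, 0.9)),
                      noise_sd = 0.2, seed = 8)
  gen <- generate_edge_level(d)
  hg <- extract_hyperedges(fdr_binarize(edge_edge_correlation(gen$ets)), 10)
  h <- recovered_hyperedge(hg, gen$group_of_edge, 1)
  expect_false(is.na(h))
  cls <- classify_hyperedges(hg, gen$ets, n_permutations = 400, seed = 3)
  expect_true(cls$labels[h] %in% c("multi-task", "none"))
})

test_that("classification applies the Bonferroni family and exclusion rules", {
  # hand-built matrix: hyperedge 1 co-evolves in tasks a and b (excluded);
  # hyperedge 2 co-evolves only in task a (a-specific); c and d are long
  # clean tasks so the null pools are dominated by signal-free windows
  set.seed(9)
  tasks <- rep(c("a", "b", "c", "d"), c(12, 12, 24, 24))
  n_win <- length(tasks)
  w <- matrix(rnorm(10 * n_win, sd = 0.15), 10, n_win)
  sig_ab <- ifelse(tasks %in% c("a", "b"), rnorm(n_win, sd = 0.4), 0)
  sig_a <- ifelse(tasks == "a", rnorm(n_win, sd = 0.4), 0)
  for (r in 1:2) w[r, ] <- w[r, ] + sig_ab
  for (r in 3:4) w[r, ] <- w[r, ] + sig_a
  w <- w / max(abs(w))
  ets <- edge_ts(w, 5, tasks)
  hg <- extract_hyperedges(fdr_binarize(edge_edge_correlation(ets)), 5)
  cls <- classify_hyperedges(hg, ets, alpha = 0.4, n_permutations = 1000,
                             seed = 2)
  memb <- hypergraph_membership(hg)
  h_ab <- memb[1]
  h_a <- memb[3]
  expect_equal(cls$labels[h_ab], "multi-task")
  expect_equal(cls$labels[h_a], "a")
  expect_equal(cls$n_tests, length(hg$hyperedges) * 4L)
  # excluded hyperedges appear in no task-specific hypergraph
  for (task in names(cls$task_hypergraphs)) {
    for (he in cls$task_hypergraphs[[task]]$hyperedges) {
      expect_false(setequal(he, hg$hyperedges[[h_ab]]))
    }
  }
  # the a-specific hyperedge appears exactly in task a's hypergraph
  expect_true(any(vapply(cls$task_hypergraphs[["a"]]$hyperedges,
                         setequal, logical(1), hg$hyperedges[[h_a]])))
  # task-specific hypergraphs are pairwise disjoint and partition edges
  for (task in names(cls$task_hypergraphs)) {
    th <- cls$task_hypergraphs[[task]]
    expect_setequal(c(unlist(th$hyperedges), th$singletons),
                    seq_len(th$n_edges))
  }
  labs <- cls$labels[cls$labels %in% c("a", "b", "c")]
  expect_equal(anyDuplicated(labs[duplicated(labs)]), 0)
})

test_that("no significant hyperedges yields empty task-specific hypergraphs", {
  set.seed(30)
  w <- matrix(rnorm(6 * 24, sd = 0.2), 6, 24)
  ets <- edge_ts(pmin(pmax(w, -1), 1), 4, rep(c("a", "b", "c"), each = 8))
  b <- matrix(0L, 6, 6)
  b[1, 2] <- b[2, 1] <- 1L
  hg <- extract_hyperedges(b, 4)
  cls <- classify_hyperedges(hg, ets, n_permutations = 200, seed = 5)
  expect_true(all(lengths(lapply(cls$task_hypergraphs, `[[`, "hyperedges")) == 0))
})
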