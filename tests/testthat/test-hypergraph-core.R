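test_that("edge-edge correlations match brute-force Pearson and t-transform p-values", {
  # identical and affine rows correlate perfectly
  w <- rbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6) * 0.1,
             c(2, 4, 6, 8, 10, 12) - 1, rep(0.5, 6),
             c(1, 0, 2, 1, 3, 2), c(0, 1, 1, 2, 2, 3)) / 15
  ets <- edge_ts(w, 4, rep("a", 6))
  eec <- edge_edge_correlation(ets)
  expect_equal(eec$r[1, 2], 1)
  expect_equal(eec$r[1, 3], 1)
  expect_lt(eec$p[1, 2], 1e-10)
  # constant row: r 0, p 1
  expect_equal(eec$r[4, 1], 0)
  expect_equal(eec$p[4, 1], 1)
  # hand-verified pair via the independent brute force
  r56 <- naive_pearson(w[5, ], w[6, ])
  expect_equal(eec$r[5, 6], r56, tolerance = 1e-12)
  expect_equal(eec$p[5, 6], naive_p_two_sided(r56, 6), tolerance = 1e-12)
  expect_error(edge_edge_correlation(edge_ts(w[, 1:3], 4, rep("a", 3))),
               "at least 4")
})

test_that("one-sided p-values only reward positive co-evolution", {
  w <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.5), c(0.5, 0.4, 0.3, 0.2, 0.1),
             c(0.1, 0.2, 0.3, 0.4, 0.5), rnorm(5, sd = 0.1),
             rnorm(5, sd = 0.1), rnorm(5, sd = 0.1))
  ets <- edge_ts(w, 4, rep("a", 5))
  two <- edge_edge_correlation(ets, "two.sided")
  one <- edge_edge_correlation(ets, "greater")
  expect_lt(two$p[1, 2], 1e-6)   # perfect anti-correlation links two-sided
  expect_equal(one$p[1, 2], 1)   # but not one-sided
  expect_lt(one$p[1, 3], 1e-6)
})

test_that("FDR binarization reproduces Benjamini-Hochberg by hand", {
  # m = 3 p-values {0.001, 0.2, 0.9}: only 0.001 survives at q = 0.05
  b1 <- fdr_binarize(eec_with_p(c(0.001, 0.2, 0.9), 3), 0.05)$b
  expect_equal(sum(b1) / 2, 1)
  expect_equal(b1[1, 2], 1L)
  # {0.01, 0.02, 0.03}: all three survive (0.03 <= 0.05 * 3/3)
  b2 <- fdr_binarize(eec_with_p(c(0.01, 0.02, 0.03), 3), 0.05)$b
  expect_equal(sum(b2) / 2, 3)
  # all p = 1: nothing survives
  b3 <- fdr_binarize(eec_with_p(rep(1, 3), 3), 0.05)$b
  expect_true(all(b3 == 0))
  expect_error(fdr_binarize(eec_with_p(rep(0.5, 3), 3), 1.5), "\\(0, 1\\)")
})

test_that("FDR binarization agrees with an independent sort-and-scan BH", {
  set.seed(31)
  for (k in 1:200) {
    m <- sample(3:28, 1)
    e <- ceiling((1 + sqrt(1 + 8 * m)) / 2)
    pu <- runif(m)^sample(1:3, 1)
    n_pairs <- edge_count(e)
    pvec <- c(pu, rep(1, n_pairs - m))
    b <- fdr_binarize(eec_with_p(pvec, e), 0.05)$b
    expect_identical(as.logical(b[upper.tri(b)]), bh_reject(pvec, 0.05))
  }
})

test_that("lowering q never adds links", {
  set.seed(77)
  pvec <- runif(edge_count(8))^2
  eec <- eec_with_p(pvec, 8)
  b_strict <- fdr_binarize(eec, 0.01)$b
  b_loose <- fdr_binarize(eec, 0.10)$b
  expect_true(all(b_strict <= b_loose))
})

test_that("hyperedges are the connected components of the binarized matrix", {
  # chain e1-e2, e2-e3 among 4 edges: one hyperedge {1,2,3}, e4 a singleton
  b <- matrix(0L, 6, 6)
  b[1, 2] <- b[2, 1] <- 1L
  b[2, 3] <- b[3, 2] <- 1L
  hg <- extract_hyperedges(b, 4)
  expect_length(hg$hyperedges, 1)
  expect_equal(hg$hyperedges[[1]], 1:3)
  expect_true(all(4:6 %in% hg$singletons))
  # all zero: everything a singleton
  hg0 <- extract_hyperedges(matrix(0L, 6, 6), 4)
  expect_length(hg0$hyperedges, 0)
  expect_equal(hg0$singletons, 1:6)
  # two disjoint linked pairs among 6 edges
  b2 <- matrix(0L, 6, 6)
  b2[1, 5] <- b2[5, 1] <- 1L
  b2[2, 4] <- b2[4, 2] <- 1L
  hg2 <- extract_hyperedges(b2, 4)
  expect_equal(hg2$hyperedges, list(c(1L, 5L), c(2L, 4L)))
  expect_equal(hg2$singletons, c(3L, 6L))
})

test_that("hyperedge extraction matches brute-force transitive closure and partitions edges", {
  set.seed(13)
  for (k in 1:100) {
    n_nodes <- sample(4:7, 1)
    e <- edge_count(n_nodes)
    b <- matrix(0L, e, e)
    links <- which(upper.tri(b) & matrix(runif(e * e) < 0.08, e, e))
    b[links] <- 1L
    b <- b + t(b)
    hg <- extract_hyperedges(b, n_nodes)
    # partition: every edge in exactly one hyperedge or the singleton set
    all_edges <- sort(c(unlist(hg$hyperedges), hg$singletons))
    expect_identical(all_edges, seq_len(e))
    expect_true(same_partition(hypergraph_membership(hg),
                               closure_membership(b)))
    expect_true(all(hyperedge_size(hg) >= 2))
  }
})

test_that("hyperedge sizes and node spans match the worked schematic", {
  # three co-evolving edges on six distinct nodes plus one singleton
  b <- matrix(0L, edge_count(8), edge_count(8))
  members <- pair_to_edge(c(1, 3, 5), c(2, 4, 6), 8)
  b[members[1], members[2]] <- b[members[2], members[1]] <- 1L
  b[members[2], members[3]] <- b[members[3], members[2]] <- 1L
  hg <- extract_hyperedges(b, 8)
  expect_equal(hyperedge_size(hg), 3L)
  expect_length(edge_nodes(hg$hyperedges[[1]], 8), 6)
})

test_that("hyperedge node degree counts hyperedges touching each node", {
  b <- matrix(0L, 3, 3)
  b[1, 3] <- b[3, 1] <- 1L  # edges (1,2) and (2,3) of a 3-node graph
  hg <- extract_hyperedges(b, 3)
  expect_equal(hyperedge_node_degree(hg), c(1L, 1L, 1L))
  # summing over subjects equals the group aggregate
  two <- hyperedge_node_degree(list(hg, hg))
  expect_equal(two, 2L * hyperedge_node_degree(hg))
})

test_that("size distribution is complementary-cumulative and additive", {
  mk <- function(sizes, n_nodes = 6) {
    e <- edge_count(n_nodes)
    hes <- list()
    nxt <- 1L
    for (s in sizes) {
      hes <- c(hes, list(nxt:(nxt + s - 1L)))
      nxt <- nxt + s
    }
    structure(list(hyperedges = hes, singletons = setdiff(seq_len(e), 1:(nxt - 1L)),
                   n_edges = e, n_nodes = n_nodes, subject_id = "x"),
              class = "hypergraph")
  }
  d <- size_distribution(mk(c(2, 2, 5)))
  expect_equal(d$size, c(2L, 5L))
  expect_equal(d$n_ge, c(3L, 1L))
  expect_true(all(diff(d$n_ge) <= 0))
  expect_equal(nrow(size_distribution(list())), 0)
  # pooled counts equal sums of per-subject counts
  pooled <- size_distribution(list(mk(c(2, 3)), mk(c(3, 4))))
  expect_equal(pooled$n_ge[pooled$size == 3], 3L)
})
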