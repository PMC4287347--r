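# Independent brute-force oracles. These deliberately avoid stats::cor,
# stats::p.adjust and igraph so they can cross-check the implementation.

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

naive_p_two_sided <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), n - 2)
}

# Benjamini-Hochberg by the sort-and-scan definition: reject the k smallest
# p-values where k is the largest index with p_(k) <= q * k / m.
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Connected-component membership by boolean transitive closure.
closure_membership <- function(b) {
  n <- nrow(b)
  reach <- (b != 0) | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  keys <- apply(reach, 1, paste, collapse = "")
  match(keys, unique(keys))
}

# Partition of edge indices implied by a hypergraph: component id per edge
# (singletons get their own ids).
hypergraph_membership <- function(hg) {
  memb <- integer(hg$n_edges)
  for (k in seq_along(hg$hyperedges)) memb[hg$hyperedges[[k]]] <- k
  nk <- length(hg$hyperedges)
  for (s in hg$singletons) {
    nk <- nk + 1L
    memb[s] <- nk
  }
  memb
}

same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

rand_ets <- function(n_nodes, n_windows, tasks = rep("a", n_windows)) {
  edge_ts(matrix(stats::runif(edge_count(n_nodes) * n_windows, -1, 1),
                 edge_count(n_nodes), n_windows),
          n_nodes, tasks)
}

# Fake edge_edge_cor with prescribed upper-triangular p-values.
eec_with_p <- function(p_upper, n_edges) {
  p <- matrix(0, n_edges, n_edges)
  p[upper.tri(p)] <- p_upper
  p <- p + t(p)
  diag(p) <- 0
  structure(list(r = matrix(0, n_edges, n_edges), p = p,
                 n_windows = 10L, alternative = "two.sided"),
            class = "edge_edge_cor")
}

two_task_design <- function(n_nodes, groups, noise_sd, seed,
                            n_windows = c(16, 16)) {
  planted_design(n_nodes,
                 tasks = data.frame(task = c("a", "b"), tr = c(2, 2),
                                    n_windows = n_windows),
                 groups = groups, noise_sd = noise_sd, seed = seed)
}

three_pair_group <- function(first_node, amplitude, task = NULL, baseline = 0) {
  nodes <- first_node + 0:5
  planted_group(rbind(nodes[1:2], nodes[3:4], nodes[5:6]),
                amplitude = amplitude, task = task, baseline = baseline)
}

# Which hyperedge (0 = none) holds each planted member; returns the shared
# id when all members sit in one hyperedge, else NA.
recovered_hyperedge <- function(hg, group_of_edge, group_id) {
  memb <- integer(hg$n_edges)
  for (k in seq_along(hg$hyperedges)) memb[hg$hyperedges[[k]]] <- k
  ids <- unique(memb[group_of_edge == group_id])
  if (length(ids) == 1 && ids[1] > 0) ids[1] else NA_integer_
}
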