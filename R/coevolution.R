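#' Co-evolution probability network over an ensemble of hypergraphs
#'
#' P(i, j) is the fraction of hypergraphs (typically one per subject) in
#' which the edge (i, j) belongs to a non-singleton hyperedge; singletons
#' contribute 0. Downstream metrics use the entry verbatim as the
#' "strength" of the co-evolution connection.
#'
#' @param hypergraphs nonempty list of `hypergraph` objects on a common node
#'   set (a single hypergraph is accepted).
#' @param label identifier for the ensemble (e.g. `"all"`, `"rest"`).
#' @return object of class `coevolution_network`: `P` (N x N symmetric
#'   matrix in `[0, 1]` with zero diagonal), `n_hypergraphs`, `n_nodes`,
#'   `label`.
#' @export
coevolution_matrix <- function(hypergraphs, label = "all") {
  if (inherits(hypergraphs, "hypergraph")) hypergraphs <- list(hypergraphs)
  if (length(hypergraphs) == 0) stop("need at least one hypergraph")
  n_nodes <- hypergraphs[[1]]$n_nodes
  counts <- numeric(edge_count(n_nodes))
  for (hg in hypergraphs) {
    if (hg$n_nodes != n_nodes) stop("hypergraphs must share the node count")
    counts <- counts + edge_in_hyperedge(hg)
  }
  prob <- counts / length(hypergraphs)
  pr <- edge_pairs(n_nodes)
  p_mat <- matrix(0, n_nodes, n_nodes)
  p_mat[cbind(pr$i, pr$j)] <- prob
  p_mat[cbind(pr$j, pr$i)] <- prob
  structure(list(P = p_mat, n_hypergraphs = length(hypergraphs),
                 n_nodes = as.integer(n_nodes), label = as.character(label)),
            class = "coevolution_network")
}

#' Construct a co-evolution network from a probability matrix
#'
#' Mostly useful for planting known connection strengths when validating
#' the spatial metrics; [coevolution_matrix()] is the usual entry point.
#'
#' @param P N x N symmetric matrix with entries in `[0, 1]`.
#' @param n_hypergraphs ensemble size recorded on the object.
#' @param label network label.
#' @return a `coevolution_network`.
#' @export
coevolution_network <- function(P, n_hypergraphs = NA_integer_, label = "custom") {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P), all(P >= 0), all(P <= 1),
            isTRUE(all.equal(P, t(P))))
  diag(P) <- 0
  dimnames(P) <- NULL
  structure(list(P = P, n_hypergraphs = n_hypergraphs,
                 n_nodes = nrow(P), label = as.character(label)),
            class = "coevolution_network")
}

#' @export
print.coevolution_network <- function(x, ...) {
  cat(sprintf("<coevolution_network> '%s': %d nodes, %d hypergraphs, max P = %.3f\n",
              x$label, x$n_nodes, x$n_hypergraphs, max(x$P)))
  invisible(x)
}

# Upper-triangular strengths in canonical edge order.
coevolution_strengths <- function(net) {
  pr <- edge_pairs(net$n_nodes)
  net$P[cbind(pr$i, pr$j)]
}

#' Top-probability bands of a co-evolution network
#'
#' Node pairs are ranked by P (descending, ties broken by canonical edge
#' index) and the top fraction is split into equal-fraction bands, matching
#' the 1% / 0.2%-band display convention for co-evolution networks.
#'
#' @param net a `coevolution_network`.
#' @param top_fraction fraction of node pairs to retain, in (0, 1].
#' @param n_bands number of equal-fraction bands.
#' @return data frame with columns `i`, `j`, `probability`, `rank`, `band`
#'   (band 1 is the strongest).
#' @export
threshold_bands <- function(net, top_fraction = 0.01, n_bands = 5) {
  stopifnot(inherits(net, "coevolution_network"),
            top_fraction > 0, top_fraction <= 1, n_bands >= 1)
  p_vec <- coevolution_strengths(net)
  pr <- edge_pairs(net$n_nodes)
  k <- max(1L, floor(top_fraction * length(p_vec)))
  ord <- order(-p_vec, seq_along(p_vec))
  n_nonzero <- sum(p_vec > 0)
  if (n_nonzero < k) {
    warning(sprintf("only %d nonzero probabilities for a requested top %d; returning all nonzero",
                    n_nonzero, k))
    k <- n_nonzero
  }
  if (k == 0) {
    return(data.frame(i = integer(0), j = integer(0), probability = numeric(0),
                      rank = integer(0), band = integer(0)))
  }
  sel <- ord[seq_len(k)]
  data.frame(i = pr$i[sel], j = pr$j[sel], probability = p_vec[sel],
             rank = seq_len(k),
             band = as.integer(ceiling(seq_len(k) * n_bands / k)))
}
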