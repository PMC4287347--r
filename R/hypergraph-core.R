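#' Edge-edge correlation matrix X with p-values
#'
#' Pearson correlation between every pair of edge-weight time series, with a
#' p-value from the t transform `t = r * sqrt((W - 2) / (1 - r^2))` on
#' `W - 2` degrees of freedom. Constant edge rows get r = 0, p = 1. The
#' E x E product is computed in row blocks so large parcellations stream
#' rather than materialize intermediate copies.
#'
#' @param ets an [edge_ts()] with at least 4 windows.
#' @param alternative `"two.sided"` (default; strongly anti-correlated edge
#'   series can also link) or `"greater"` (positive correlations only).
#' @param block_size rows per block of the correlation product.
#' @return object of class `edge_edge_cor`: `r`, `p` (E x E symmetric
#'   matrices), `n_windows`, `alternative`.
#' @export
edge_edge_correlation <- function(ets, alternative = c("two.sided", "greater"),
                                  block_size = 4096L) {
  stopifnot(inherits(ets, "edge_ts"))
  alternative <- match.arg(alternative)
  w <- ets$weights
  n_win <- ncol(w)
  if (n_win < 4) stop("need at least 4 windows for edge-edge p-values")
  e <- nrow(w)
  s <- apply(w, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  z <- w - rowMeans(w)
  denom <- sqrt(rowSums(z^2))
  denom[denom == 0] <- 1
  z <- z / denom
  r <- matrix(0, e, e)
  starts <- seq(1L, e, by = as.integer(block_size))
  for (b in starts) {
    rows <- b:min(b + block_size - 1L, e)
    r[rows, ] <- tcrossprod(z[rows, , drop = FALSE], z)
  }
  r <- pmin(pmax(r, -1), 1)
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  df <- n_win - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- sign(r[abs(r) >= 1]) * Inf
  p <- if (alternative == "two.sided") {
    2 * stats::pt(-abs(tt), df)
  } else {
    stats::pt(tt, df, lower.tail = FALSE)
  }
  p <- pmin(p, 1)
  p[const, ] <- 1
  p[, const] <- 1
  diag(p) <- 0
  structure(list(r = r, p = p, n_windows = n_win, alternative = alternative),
            class = "edge_edge_cor")
}

#' Binarize the edge-edge matrix at an FDR level (Benjamini-Hochberg)
#'
#' The BH procedure is applied once over the E(E-1)/2 upper-triangular
#' p-values of one subject's X; pairs passing the FDR cutoff get b = 1.
#'
#' @param eec an `edge_edge_cor` from [edge_edge_correlation()].
#' @param q FDR level in (0, 1); default 0.05.
#' @return object of class `binarized_edge_matrix`: `b` (E x E symmetric 0/1
#'   integer matrix, zero diagonal), `q`, `alternative`.
#' @export
fdr_binarize <- function(eec, q = 0.05) {
  stopifnot(inherits(eec, "edge_edge_cor"))
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  p <- eec$p
  if (any(!is.finite(p))) stop("p-values must be finite")
  e <- nrow(p)
  ut <- upper.tri(p)
  padj <- stats::p.adjust(p[ut], method = "BH")
  b <- matrix(0L, e, e)
  b[ut] <- as.integer(padj <= q)
  b <- b + t(b)
  structure(list(b = b, q = q, alternative = eec$alternative),
            class = "binarized_edge_matrix")
}

#' Extract hyperedges as connected components of the binarized edge graph
#'
#' Vertices are edges of the original network; links are entries b = 1.
#' Components of size >= 2 become hyperedges (sets of edges whose weight
#' series co-evolve); isolated vertices are singletons, excluded from
#' further analyses. Hyperedges and singletons partition all E edges.
#'
#' @param b a `binarized_edge_matrix` from [fdr_binarize()], or a raw E x E
#'   symmetric 0/1 matrix.
#' @param n_nodes number of nodes of the underlying network
#'   (`edge_count(n_nodes)` must equal E).
#' @param subject_id optional subject identifier carried in the result.
#' @return object of class `hypergraph`: `hyperedges` (list of sorted
#'   integer edge-index vectors, ordered by smallest member), `singletons`,
#'   `n_edges`, `n_nodes`, `subject_id`.
#' @export
extract_hyperedges <- function(b, n_nodes, subject_id = NA_character_) {
  mat <- if (inherits(b, "binarized_edge_matrix")) b$b else as.matrix(b)
  e <- nrow(mat)
  if (e != edge_count(n_nodes)) {
    stop(sprintf("matrix has %d rows but %d nodes imply %d edges",
                 e, n_nodes, edge_count(n_nodes)))
  }
  if (!isTRUE(all.equal(mat, t(mat)))) stop("binarized matrix must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(mat != 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  groups <- split(seq_len(e), comp$membership)
  sizes <- lengths(groups)
  hyperedges <- unname(groups[sizes >= 2])
  if (length(hyperedges) > 0) {
    hyperedges <- hyperedges[order(vapply(hyperedges, min, integer(1)))]
    hyperedges <- lapply(hyperedges, function(x) sort(as.integer(x)))
  }
  singletons <- sort(as.integer(unlist(groups[sizes == 1], use.names = FALSE)))
  structure(list(hyperedges = hyperedges, singletons = singletons,
                 n_edges = as.integer(e), n_nodes = as.integer(n_nodes),
                 subject_id = as.character(subject_id)),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> subject %s: %d hyperedges (sizes %s), %d singletons, %d edges on %d nodes\n",
              x$subject_id, length(x$hyperedges),
              paste(hyperedge_size(x), collapse = ", "),
              length(x$singletons), x$n_edges, x$n_nodes))
  invisible(x)
}

#' Hyperedge sizes (number of member edges)
#'
#' @param h a `hypergraph` (returns all non-singleton sizes) or a single
#'   hyperedge as an integer vector of edge indices.
#' @return integer vector of sizes.
#' @export
hyperedge_size <- function(h) {
  if (inherits(h, "hypergraph")) lengths(h$hyperedges) else length(h)
}

# Logical membership vector: is each edge part of a non-singleton hyperedge?
edge_in_hyperedge <- function(hg) {
  member <- logical(hg$n_edges)
  for (he in hg$hyperedges) member[he] <- TRUE
  member
}

#' Hyperedge node degree
#'
#' For each node, the number of non-singleton hyperedges (summed over the
#' supplied hypergraphs) in which at least one member edge touches the node.
#'
#' @param hypergraphs a `hypergraph` or list of hypergraphs on a common node
#'   set.
#' @param n_nodes number of nodes; defaults to that of the first hypergraph.
#' @return integer vector of length `n_nodes`.
#' @export
hyperedge_node_degree <- function(hypergraphs, n_nodes = NULL) {
  if (inherits(hypergraphs, "hypergraph")) hypergraphs <- list(hypergraphs)
  stopifnot(length(hypergraphs) >= 1)
  if (is.null(n_nodes)) n_nodes <- hypergraphs[[1]]$n_nodes
  deg <- integer(n_nodes)
  for (hg in hypergraphs) {
    if (hg$n_nodes != n_nodes) stop("hypergraphs must share the node count")
    for (he in hg$hyperedges) {
      nodes <- edge_nodes(he, n_nodes)
      deg[nodes] <- deg[nodes] + 1L
    }
  }
  deg
}

#' Cumulative hyperedge size distribution
#'
#' Complementary cumulative counts of non-singleton hyperedge sizes pooled
#' across hypergraphs: for each observed size s, the number of hyperedges of
#' size >= s.
#'
#' @param hypergraphs a `hypergraph` or list of hypergraphs.
#' @return data frame with columns `size` and `n_ge` (monotone
#'   non-increasing); zero rows if there are no non-singleton hyperedges.
#' @export
size_distribution <- function(hypergraphs) {
  if (inherits(hypergraphs, "hypergraph")) hypergraphs <- list(hypergraphs)
  sizes <- unlist(lapply(hypergraphs, hyperedge_size), use.names = FALSE)
  if (length(sizes) == 0) {
    return(data.frame(size = integer(0), n_ge = integer(0)))
  }
  ss <- sort(unique(sizes))
  data.frame(size = ss,
             n_ge = vapply(ss, function(s) sum(sizes >= s), integer(1)))
}
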