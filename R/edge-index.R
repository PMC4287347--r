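#' Number of node pairs (edges) in a network of `n_nodes` nodes
#'
#' @param n_nodes number of nodes (regions).
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @examples
#' edge_count(194)  # 18721 edges at the study's parcellation scale
#' @export
edge_count <- function(n_nodes) {
  stopifnot(length(n_nodes) == 1, n_nodes >= 1, n_nodes == round(n_nodes))
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Canonical edge index for an undirected network
#'
#' Edges are unordered node pairs `(i, j)` with `i < j`, enumerated in
#' lexicographic order: (1,2), (1,3), ..., (1,n), (2,3), ... This single
#' convention is used for every edge-indexed object in the package, so
#' hypergraphs are comparable across subjects.
#'
#' @param n_nodes number of nodes.
#' @return data frame with integer columns `i`, `j`, one row per edge.
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  n <- as.integer(n_nodes)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Row index of an edge in the canonical edge ordering
#'
#' @param i,j node indices (1-based); order is irrelevant.
#' @param n_nodes number of nodes.
#' @return integer edge row index (vectorized over `i`, `j`).
#' @export
pair_to_edge <- function(i, j, n_nodes) {
  stopifnot(all(i != j), all(i >= 1), all(j >= 1), all(i <= n_nodes), all(j <= n_nodes))
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  as.integer((lo - 1) * n_nodes - lo * (lo - 1) / 2 + (hi - lo))
}

#' Nodes touched by a set of edges
#'
#' @param edges integer edge row indices (canonical ordering).
#' @param n_nodes number of nodes.
#' @return sorted integer vector of node indices incident to any of the edges.
#' @export
edge_nodes <- function(edges, n_nodes) {
  pr <- edge_pairs(n_nodes)
  sort(unique(c(pr$i[edges], pr$j[edges])))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# 32-bit FNV-1a over a string, using double arithmetic (R ints are 32-bit).
fnv1a32 <- function(x) {
  mul32 <- function(a, b) {
    hi <- floor(a / 65536)
    lo <- a %% 65536
    ((((hi * b) %% 4294967296) * 65536) %% 4294967296 + lo * b) %% 4294967296
  }
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  }
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- xor32(h, b)
    h <- mul32(h, 16777619)
  }
  h
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' A single master seed reproduces every stochastic stage of the pipeline;
#' each stage (or subject) draws from an independent stream keyed by a label.
#'
#' @param master_seed integer master seed.
#' @param label character stage label (e.g. `"subject-3"`, `"null-overall"`).
#' @return integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master_seed, label) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed))
  h <- fnv1a32(paste0(format(master_seed, scientific = FALSE), "/", label))
  as.integer(h %% 2147483646) + 1L
}

# Short deterministic fingerprint of a configuration list.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  sprintf("%08x", fnv1a32(s))
}
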