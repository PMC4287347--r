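#' Write / read a region run as delimited text plus a JSON sidecar
#'
#' `<prefix>.tsv` holds the region x sample matrix (one row per region, tab
#' separated); `<prefix>.json` holds subject, task and sampling period;
#' `<prefix>.fd.txt` holds the framewise-displacement trace (single
#' column), if present.
#'
#' @param run a [region_run()].
#' @param prefix file path prefix (no extension).
#' @return the prefix, invisibly.
#' @export
write_region_run <- function(run, prefix) {
  stopifnot(inherits(run, "region_run"))
  utils::write.table(run$data, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = run$subject_id, task = run$task,
               sampling_period = run$sampling_period,
               n_regions = nrow(run$data), n_samples = ncol(run$data),
               has_fd = !is.null(run$fd))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(run$fd)) {
    writeLines(format(run$fd, digits = 17), paste0(prefix, ".fd.txt"))
  }
  invisible(prefix)
}

#' @rdname write_region_run
#' @export
read_region_run <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  fd <- if (isTRUE(meta$has_fd)) {
    as.numeric(readLines(paste0(prefix, ".fd.txt")))
  } else NULL
  region_run(data, meta$sampling_period, meta$task,
             subject_id = meta$subject_id, fd = fd)
}

#' Write / read an edge time series as CSV plus a JSON sidecar
#'
#' The CSV holds the E x W weight matrix (columns `w1..wW`); the sidecar
#' (`<path>.json`) records the node count and the window task labels.
#'
#' @param ets an [edge_ts()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_edge_ts <- function(ets, path) {
  stopifnot(inherits(ets, "edge_ts"))
  w <- ets$weights
  colnames(w) <- paste0("w", seq_len(ncol(w)))
  utils::write.csv(w, path, row.names = FALSE)
  jsonlite::write_json(list(n_nodes = ets$n_nodes,
                            window_tasks = ets$window_tasks),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edge_ts
#' @export
read_edge_ts <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- as.matrix(utils::read.csv(path))
  dimnames(w) <- NULL
  edge_ts(w, meta$n_nodes, meta$window_tasks)
}

#' Write / read a hypergraph as JSON
#'
#' Hyperedges and singletons are stored as lists of node pairs (1-based),
#' so the file is self-describing without the canonical edge index.
#'
#' @param hg a `hypergraph`.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_hypergraph <- function(hg, path) {
  stopifnot(inherits(hg, "hypergraph"))
  pr <- edge_pairs(hg$n_nodes)
  as_pairs <- function(edges) {
    lapply(edges, function(e) c(pr$i[e], pr$j[e]))
  }
  jsonlite::write_json(
    list(n_nodes = hg$n_nodes, subject_id = hg$subject_id,
         hyperedges = lapply(hg$hyperedges, as_pairs),
         singletons = as_pairs(hg$singletons)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_hypergraph
#' @export
read_hypergraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n_nodes <- obj$n_nodes[[1]]
  to_idx <- function(pairs) {
    as.integer(vapply(pairs, function(p) {
      pair_to_edge(p[[1]], p[[2]], n_nodes)
    }, numeric(1)))
  }
  hyperedges <- lapply(obj$hyperedges, function(he) sort(to_idx(he)))
  singletons <- sort(to_idx(obj$singletons))
  structure(list(hyperedges = hyperedges, singletons = singletons,
                 n_edges = edge_count(n_nodes), n_nodes = as.integer(n_nodes),
                 subject_id = as.character(obj$subject_id[[1]])),
            class = "hypergraph")
}

#' Export the binarized edge-edge graph as GraphML
#'
#' @param b a `binarized_edge_matrix` (or raw symmetric 0/1 matrix).
#' @param path GraphML path.
#' @export
write_binarized_graphml <- function(b, path) {
  mat <- if (inherits(b, "binarized_edge_matrix")) b$b else as.matrix(b)
  g <- igraph::graph_from_adjacency_matrix(mat != 0, mode = "undirected",
                                           diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a co-evolution network as a CSV matrix and optional GraphML
#'
#' @param net a `coevolution_network`.
#' @param csv_path path for the N x N probability matrix CSV.
#' @param graphml_path optional path for a weighted GraphML export.
#' @export
write_coevolution <- function(net, csv_path, graphml_path = NULL) {
  stopifnot(inherits(net, "coevolution_network"))
  utils::write.csv(net$P, csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_adjacency_matrix(net$P, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(csv_path)
}

#' Read a co-evolution network matrix written by [write_coevolution()]
#'
#' @param csv_path CSV path of the probability matrix.
#' @param label network label.
#' @param n_hypergraphs ensemble size recorded on the object.
#' @export
read_coevolution <- function(csv_path, label = "all", n_hypergraphs = NA_integer_) {
  p_mat <- as.matrix(utils::read.csv(csv_path))
  dimnames(p_mat) <- NULL
  structure(list(P = p_mat, n_hypergraphs = n_hypergraphs,
                 n_nodes = nrow(p_mat), label = label),
            class = "coevolution_network")
}

#' Read node centroid geometry from CSV (`node, x, y, z`)
#'
#' @param path CSV path.
#' @return a [node_geometry()].
#' @export
read_node_geometry <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  node_geometry(df$x, df$y, df$z,
                node_ids = if ("node" %in% names(df)) df$node else NULL)
}

#' Write node centroid geometry to CSV
#'
#' @param geom a [node_geometry()].
#' @param path CSV path.
#' @export
write_node_geometry <- function(geom, path) {
  utils::write.csv(as.data.frame(geom), path, row.names = FALSE)
  invisible(path)
}
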