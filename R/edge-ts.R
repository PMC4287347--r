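#' Edge-weight time series matrix
#'
#' Container for the E x W matrix of windowed edge weights: row `e` holds the
#' Pearson correlation of one node pair across the W time windows, in the
#' canonical lexicographic edge order of [edge_pairs()]. Each window carries
#' the task label of the run it was cut from.
#'
#' @param weights E x W numeric matrix, entries in `[-1, 1]`.
#' @param n_nodes number of nodes; `nrow(weights)` must equal
#'   `edge_count(n_nodes)`.
#' @param window_tasks character vector of per-window task labels, length W.
#' @return an object of class `edge_ts` with fields `weights`, `n_nodes`,
#'   `window_tasks`.
#' @export
edge_ts <- function(weights, n_nodes, window_tasks) {
  weights <- as.matrix(weights)
  if (anyNA(weights)) stop("edge weights must not contain missing values")
  if (nrow(weights) != edge_count(n_nodes)) {
    stop(sprintf("expected %d edge rows for %d nodes, got %d",
                 edge_count(n_nodes), n_nodes, nrow(weights)))
  }
  if (length(window_tasks) != ncol(weights)) {
    stop("window_tasks must have one label per window (column)")
  }
  if (any(abs(weights) > 1 + 1e-9)) {
    stop("edge weights must lie in [-1, 1]")
  }
  dimnames(weights) <- NULL
  structure(list(weights = weights,
                 n_nodes = as.integer(n_nodes),
                 window_tasks = as.character(window_tasks)),
            class = "edge_ts")
}

#' @export
print.edge_ts <- function(x, ...) {
  cat(sprintf("<edge_ts> %d edges (%d nodes) x %d windows; tasks: %s\n",
              nrow(x$weights), x$n_nodes, ncol(x$weights),
              paste(unique(x$window_tasks), collapse = ", ")))
  invisible(x)
}

#' @export
dim.edge_ts <- function(x) dim(x$weights)
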