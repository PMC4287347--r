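#' Windowed functional network: Pearson adjacency of one window
#'
#' Entry (i, j) is the Pearson correlation between the signals of regions i
#' and j over the window's samples. The diagonal is stored as zero (self
#' correlations carry no information). A region that is constant within the
#' window has undefined correlations; its row and column are set to 0 with a
#' warning naming the region (and window, if supplied) rather than aborting
#' a batch.
#'
#' @param x region x sample numeric matrix with at least 3 samples.
#' @param window optional window index used in the constant-region warning.
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
window_adjacency <- function(x, window = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("window data must not contain missing values")
  if (ncol(x) < 3) stop("a window needs at least 3 samples")
  s <- apply(x, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  a <- suppressWarnings(stats::cor(t(x)))
  if (any(const)) {
    where <- if (is.null(window)) "" else sprintf(" in window %s", window)
    warning(sprintf("constant signal for node(s) %s%s; correlations set to 0",
                    paste(which(const), collapse = ", "), where))
    a[const, ] <- 0
    a[, const] <- 0
  }
  a[!is.finite(a)] <- 0
  diag(a) <- 0
  a
}

#' Windowed network sequence
#'
#' @param windows list of windows as returned by [segment_windows()]
#'   (possibly concatenated across runs), each `list(data, task)`.
#' @return object of class `window_seq`: `adjacency` (list of N x N
#'   matrices), `window_tasks`, `n_nodes`.
#' @export
windowed_networks <- function(windows) {
  stopifnot(length(windows) >= 1)
  n <- nrow(windows[[1]]$data)
  adjacency <- lapply(seq_along(windows), function(w) {
    if (nrow(windows[[w]]$data) != n) {
      stop("all windows must share the same number of regions")
    }
    window_adjacency(windows[[w]]$data, window = w)
  })
  structure(list(adjacency = adjacency,
                 window_tasks = vapply(windows, `[[`, character(1), "task"),
                 n_nodes = as.integer(n)),
            class = "window_seq")
}

#' Extract the edge-weight time series matrix from a network sequence
#'
#' Row e, column w holds the (i, j) entry of window w's adjacency for edge
#' e = (i, j) in canonical lexicographic order.
#'
#' @param seq a `window_seq` from [windowed_networks()].
#' @return an [edge_ts()] of dimension `edge_count(N)` x W.
#' @export
edge_time_series <- function(seq) {
  stopifnot(inherits(seq, "window_seq"))
  if (length(seq$adjacency) < 2) stop("need at least 2 windows")
  pr <- edge_pairs(seq$n_nodes)
  idx <- cbind(pr$i, pr$j)
  weights <- vapply(seq$adjacency, function(a) {
    if (nrow(a) != seq$n_nodes) stop("inconsistent node count across windows")
    a[idx]
  }, numeric(nrow(pr)))
  edge_ts(weights, seq$n_nodes, seq$window_tasks)
}

#' Re-pack an edge time series into the adjacency sequence
#'
#' Inverse of [edge_time_series()] for the off-diagonal entries.
#'
#' @param ets an [edge_ts()].
#' @return a `window_seq`.
#' @export
networks_from_edge_ts <- function(ets) {
  stopifnot(inherits(ets, "edge_ts"))
  pr <- edge_pairs(ets$n_nodes)
  adjacency <- lapply(seq_len(ncol(ets$weights)), function(w) {
    a <- matrix(0, ets$n_nodes, ets$n_nodes)
    a[cbind(pr$i, pr$j)] <- ets$weights[, w]
    a[cbind(pr$j, pr$i)] <- ets$weights[, w]
    a
  })
  structure(list(adjacency = adjacency, window_tasks = ets$window_tasks,
                 n_nodes = ets$n_nodes),
            class = "window_seq")
}

#' Full path from runs to the edge-weight time series
#'
#' Convenience wrapper: optionally band-pass filter each run, segment each
#' run into windows (windows never straddle run boundaries), pool the
#' windows in run order, and extract the edge time series.
#'
#' @param runs list of [region_run()] objects of one subject.
#' @param window a [windowing_spec()].
#' @param band a [bandpass_spec()], or `NULL` to skip filtering.
#' @return an [edge_ts()].
#' @export
edge_ts_from_runs <- function(runs, window = windowing_spec(), band = bandpass_spec()) {
  stopifnot(length(runs) >= 1)
  if (!is.null(band)) runs <- lapply(runs, bandpass, spec = band)
  windows <- unlist(lapply(runs, segment_windows, spec = window),
                    recursive = FALSE)
  edge_time_series(windowed_networks(windows))
}
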