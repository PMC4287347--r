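#' Null overall model: shuffle each edge series over all windows
#'
#' Each edge row is permuted independently across all W windows (independent
#' draws from one seeded stream; a common permutation would preserve all
#' edge-edge correlations and break the null). Window task labels are
#' unchanged and each row's multiset of values is preserved exactly.
#'
#' @param ets an [edge_ts()].
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return the shuffled [edge_ts()].
#' @export
shuffle_overall <- function(ets, seed = NULL) {
  stopifnot(inherits(ets, "edge_ts"))
  w <- ets$weights
  n_win <- ncol(w)
  with_seed(seed, {
    for (e in seq_len(nrow(w))) {
      w[e, ] <- w[e, sample.int(n_win)]
    }
  })
  ets$weights <- w
  ets
}

#' Null within-task model: shuffle each edge series within each task
#'
#' Each edge row is permuted independently within each task's block of
#' windows, keeping tasks distinct: values can never cross task boundaries,
#' so between-task differences in edge weight survive the shuffle while
#' within-task temporal structure is destroyed.
#'
#' @inheritParams shuffle_overall
#' @return the shuffled [edge_ts()].
#' @export
shuffle_within_task <- function(ets, seed = NULL) {
  stopifnot(inherits(ets, "edge_ts"))
  if (length(ets$window_tasks) == 0) stop("window task labels are required")
  w <- ets$weights
  blocks <- split(seq_len(ncol(w)),
                  factor(ets$window_tasks, levels = unique(ets$window_tasks)))
  with_seed(seed, {
    for (e in seq_len(nrow(w))) {
      for (cols in blocks) {
        w[e, cols] <- w[e, cols[sample.int(length(cols))]]
      }
    }
  })
  ets$weights <- w
  ets
}

#' Run the hypergraph pipeline on a null surrogate
#'
#' Applies the requested shuffle, then the edge-edge correlation, FDR
#' binarization and hyperedge extraction end-to-end. Comparing the output
#' with the original hypergraph shows whether hyperedges can be attributed
#' to the dynamics of the system (overall null) or to between-task
#' differences (within-task null).
#'
#' @param ets an [edge_ts()].
#' @param kind `"overall"` or `"within-task"`.
#' @param seed integer seed for the shuffle.
#' @param q FDR level passed to [fdr_binarize()].
#' @param alternative sidedness passed to [edge_edge_correlation()].
#' @param subject_id carried into the output hypergraph.
#' @return object of class `null_run`: `hypergraph`, `size_distribution`,
#'   `kind`, `seed`, `q`.
#' @export
run_null <- function(ets, kind = c("overall", "within-task"), seed = 1L,
                     q = 0.05, alternative = "two.sided",
                     subject_id = NA_character_) {
  kind <- match.arg(kind)
  shuffled <- switch(kind,
                     "overall" = shuffle_overall(ets, seed = seed),
                     "within-task" = shuffle_within_task(ets, seed = seed))
  eec <- edge_edge_correlation(shuffled, alternative = alternative)
  hg <- extract_hyperedges(fdr_binarize(eec, q = q), shuffled$n_nodes,
                           subject_id = subject_id)
  structure(list(hypergraph = hg, size_distribution = size_distribution(hg),
                 kind = kind, seed = seed, q = q),
            class = "null_run")
}

#' @export
print.null_run <- function(x, ...) {
  cat(sprintf("<null_run> kind '%s' (seed %s, q %.3g): %d non-singleton hyperedges\n",
              x$kind, format(x$seed), x$q, length(x$hypergraph$hyperedges)))
  invisible(x)
}
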