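# Mean pairwise Pearson correlation between member edge series over a set
# of window columns. Undefined (constant-row) pairs contribute 0.
mean_pairwise_edge_cor <- function(weights, edges, cols) {
  sub <- weights[edges, cols, drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(sub)))
  cc[!is.finite(cc)] <- 0
  mean(cc[upper.tri(cc)])
}

#' Within-task co-evolution statistic of a hyperedge
#'
#' Mean over all unordered pairs of member edges of the Pearson correlation
#' between their weight series restricted to the task's windows.
#'
#' @param edges integer edge indices of the hyperedge (at least 2).
#' @param ets an [edge_ts()].
#' @param task task label; must have at least 4 windows.
#' @return the mean pairwise within-task correlation.
#' @export
within_task_statistic <- function(edges, ets, task) {
  stopifnot(inherits(ets, "edge_ts"), length(edges) >= 2)
  cols <- which(ets$window_tasks == task)
  if (length(cols) < 4) {
    stop(sprintf("task '%s' has %d windows; need at least 4", task, length(cols)))
  }
  mean_pairwise_edge_cor(ets$weights, edges, cols)
}

#' Permutation test for task-specific co-evolution of a hyperedge
#'
#' Compares the within-task statistic to a null built by drawing, without
#' replacement, a window set of the same cardinality from the other tasks'
#' windows and recomputing the statistic. One-sided: the task is specific
#' when the observed correlation is higher than the null. The p-value is
#' `(1 + #{null >= observed}) / (1 + n_permutations)`, never exactly zero.
#'
#' @inheritParams within_task_statistic
#' @param n_permutations number of null draws (>= 1).
#' @param seed optional integer; the caller's RNG state is restored.
#' @return list with `statistic`, `p`, `n_permutations`.
#' @export
task_permutation_test <- function(edges, ets, task, n_permutations = 1000,
                                  seed = NULL) {
  stopifnot(n_permutations >= 1, n_permutations == round(n_permutations))
  observed <- within_task_statistic(edges, ets, task)
  target <- which(ets$window_tasks == task)
  others <- which(ets$window_tasks != task)
  if (length(others) < length(target)) {
    stop(sprintf(
      "task '%s' has %d windows but only %d non-target windows are available",
      task, length(target), length(others)))
  }
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      cols <- sample(others, length(target))
      mean_pairwise_edge_cor(ets$weights, edges, cols)
    }, numeric(1))
  })
  list(statistic = observed,
       p = (1 + sum(null_stats >= observed)) / (1 + n_permutations),
       n_permutations = as.integer(n_permutations))
}

#' Classify hyperedges as task-specific, multi-task, or unclassified
#'
#' Each (hyperedge, task) permutation p-value is compared to the
#' Bonferroni-corrected level `alpha / n_tests`, with
#' `n_tests = (number of non-singleton hyperedges) x (number of tasks)`
#' within one subject's hypergraph. A hyperedge significant in exactly one
#' task enters that task's task-specific hypergraph; one significant in two
#' or more tasks is excluded from all of them; the rest are unlabeled.
#'
#' @param hg a `hypergraph`.
#' @param ets the subject's [edge_ts()] (at least 2 task labels).
#' @param alpha family-wise error level.
#' @param n_permutations permutations per test.
#' @param seed integer seed making all permutation draws reproducible.
#' @return object of class `task_specificity`: `table` (data frame with
#'   `hyperedge`, `task`, `statistic`, `p`, `significant`), `labels` (per
#'   hyperedge: a task name, `"multi-task"`, or `"none"`),
#'   `task_hypergraphs` (named list of `hypergraph` objects whose
#'   hyperedges are the task-specific ones; all other edges are
#'   singletons), plus `alpha`, `n_tests`, `n_permutations`, `seed`.
#' @export
classify_hyperedges <- function(hg, ets, alpha = 0.05, n_permutations = 1000,
                                seed = 1L) {
  stopifnot(inherits(hg, "hypergraph"), inherits(ets, "edge_ts"),
            alpha > 0, alpha < 1)
  tasks <- unique(ets$window_tasks)
  if (length(tasks) < 2) stop("need at least 2 tasks to classify hyperedges")
  n_he <- length(hg$hyperedges)
  n_tests <- n_he * length(tasks)
  rows <- vector("list", n_tests)
  labels <- character(n_he)
  if (n_he > 0) {
    with_seed(seed, {
      k <- 0L
      for (h in seq_len(n_he)) {
        for (task in tasks) {
          k <- k + 1L
          # a task wider than the pooled remainder cannot be tested
          res <- tryCatch(
            task_permutation_test(hg$hyperedges[[h]], ets, task,
                                  n_permutations = n_permutations,
                                  seed = NULL),
            error = function(e) list(statistic = NA_real_, p = NA_real_))
          rows[[k]] <- data.frame(hyperedge = h, task = task,
                                  statistic = res$statistic, p = res$p)
        }
      }
    })
  }
  table <- if (n_tests > 0) do.call(rbind, rows) else
    data.frame(hyperedge = integer(0), task = character(0),
               statistic = numeric(0), p = numeric(0))
  threshold <- if (n_tests > 0) alpha / n_tests else NA_real_
  table$significant <- !is.na(table$p) & table$p <= threshold
  for (h in seq_len(n_he)) {
    sig_tasks <- table$task[table$hyperedge == h & table$significant]
    labels[h] <- if (length(sig_tasks) == 1) sig_tasks
                 else if (length(sig_tasks) >= 2) "multi-task"
                 else "none"
  }
  task_hypergraphs <- lapply(tasks, function(task) {
    keep <- which(labels == task)
    members <- hg$hyperedges[keep]
    structure(list(hyperedges = members,
                   singletons = setdiff(seq_len(hg$n_edges),
                                        unlist(members, use.names = FALSE)),
                   n_edges = hg$n_edges, n_nodes = hg$n_nodes,
                   subject_id = hg$subject_id),
              class = "hypergraph")
  })
  names(task_hypergraphs) <- tasks
  structure(list(table = table, labels = labels,
                 task_hypergraphs = task_hypergraphs,
                 alpha = alpha, n_tests = as.integer(n_tests),
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "task_specificity")
}

#' @export
print.task_specificity <- function(x, ...) {
  cat(sprintf("<task_specificity> %d hyperedges, %d tests, alpha %.3g (per-test %.3g)\n",
              length(x$labels), x$n_tests, x$alpha,
              if (x$n_tests > 0) x$alpha / x$n_tests else NA))
  if (length(x$labels) > 0) {
    print(table(factor(x$labels)))
  }
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error level.
#' @param n_tests number of tests in the family (for the pairwise task
#'   comparisons of a 4-task study over 2 spatial metrics this is 12).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
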