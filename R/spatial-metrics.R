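#' Node centroid geometry
#'
#' Coordinates follow the radiological convention used throughout: `x`
#' left-right, `y` anterior-posterior with anterior positive (so posterior
#' regions have negative y), `z` inferior-superior; units are consistent
#' (mm for real atlases).
#'
#' @param x,y,z numeric coordinate vectors, one entry per node.
#' @param node_ids optional node identifiers.
#' @return object of class `node_geometry` (a data frame).
#' @export
node_geometry <- function(x, y, z, node_ids = NULL) {
  stopifnot(length(x) == length(y), length(y) == length(z),
            all(is.finite(x)), all(is.finite(y)), all(is.finite(z)))
  geom <- data.frame(node = if (is.null(node_ids)) seq_along(x) else node_ids,
                     x = x, y = y, z = z)
  class(geom) <- c("node_geometry", "data.frame")
  geom
}

#' Euclidean distance between two node centroids
#'
#' @param geom a [node_geometry()].
#' @param i,j node indices.
#' @return Cartesian distance.
#' @export
connection_length <- function(geom, i, j) {
  sqrt((geom$x[i] - geom$x[j])^2 + (geom$y[i] - geom$y[j])^2 +
         (geom$z[i] - geom$z[j])^2)
}

# Per-connection covariate in canonical edge order.
metric_covariate <- function(geom, n_nodes, metric) {
  pr <- edge_pairs(n_nodes)
  switch(metric,
         "length-strength" = connection_length(geom, pr$i, pr$j),
         "position-strength" = (geom$y[pr$i] + geom$y[pr$j]) / 2,
         stop("unknown metric: ", metric))
}

metric_result <- function(metric, r, label, defined = TRUE, p = NA_real_) {
  structure(list(metric = metric, R = r, p = p, defined = defined,
                 label = label),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<metric_result> %s ('%s'): undefined (degenerate input)\n",
                x$metric, x$label))
  } else {
    cat(sprintf("<metric_result> %s ('%s'): R = %.4f%s\n", x$metric, x$label,
                x$R, if (is.na(x$p)) "" else sprintf(", p = %.4g", x$p)))
  }
  invisible(x)
}

spatial_metric <- function(net, geom, metric) {
  stopifnot(inherits(net, "coevolution_network"))
  if (nrow(geom) != net$n_nodes) {
    stop("geometry must have one entry per network node")
  }
  s <- coevolution_strengths(net)
  v <- metric_covariate(geom, net$n_nodes, metric)
  if (length(s) < 3 || stats::sd(s) == 0 || stats::sd(v) == 0) {
    return(metric_result(metric, NA_real_, net$label, defined = FALSE))
  }
  metric_result(metric, stats::cor(s, v), net$label)
}

#' Length-strength metric
#'
#' Pearson R between the strength of every connection of the full,
#' unthresholded co-evolution network and the Euclidean distance between
#' the two node centroids. Negative R means the strongest co-evolving
#' connections are physically short.
#'
#' @param net a `coevolution_network`.
#' @param geom a [node_geometry()] with one entry per node.
#' @return a `metric_result`; `defined = FALSE` when strengths or lengths
#'   are constant (the correlation is then undefined, not a number).
#' @export
length_strength <- function(net, geom) spatial_metric(net, geom, "length-strength")

#' Position-strength metric
#'
#' Pearson R between connection strength and the mean anterior-posterior
#' (y) position of the two nodes. Negative R means strong connections sit
#' posterior.
#'
#' @inheritParams length_strength
#' @return a `metric_result`.
#' @export
position_strength <- function(net, geom) spatial_metric(net, geom, "position-strength")

#' Permutation significance of a spatial metric
#'
#' The null distribution permutes the strength values across connections
#' (geometry fixed) and recomputes R; two-sided
#' `p = (1 + #{|R_null| >= |R_obs|}) / (1 + n_permutations)`.
#'
#' @inheritParams length_strength
#' @param metric `"length-strength"` or `"position-strength"`.
#' @param n_permutations number of permutations (>= 1).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return a `metric_result` with the permutation `p` filled in.
#' @export
metric_significance <- function(net, geom,
                                metric = c("length-strength", "position-strength"),
                                n_permutations = 1000, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(n_permutations >= 1, n_permutations == round(n_permutations))
  obs <- spatial_metric(net, geom, metric)
  if (!obs$defined) stop("metric is undefined on this network (degenerate input)")
  s <- coevolution_strengths(net)
  v <- metric_covariate(geom, net$n_nodes, metric)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) stats::cor(sample(s), v),
           numeric(1))
  })
  obs$p <- (1 + sum(abs(null_r) >= abs(obs$R))) / (1 + n_permutations)
  obs
}

#' Pairwise between-task comparison of a spatial metric
#'
#' Observed statistic: `|R_A - R_B|`. The null swaps the two networks'
#' strength values connection-wise with probability 1/2 per connection and
#' recomputes, preserving each connection's geometry while exchanging task
#' identity. The caller applies a Bonferroni correction over all task pairs
#' and metrics (see [bonferroni_threshold()]).
#'
#' @param net_a,net_b `coevolution_network` objects on the same node set.
#' @inheritParams metric_significance
#' @return list with `statistic` (= `|R_A - R_B|`), `R_a`, `R_b`, `p`,
#'   `metric`.
#' @export
pairwise_task_comparison <- function(net_a, net_b, geom,
                                     metric = c("length-strength", "position-strength"),
                                     n_permutations = 1000, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(n_permutations >= 1)
  if (net_a$n_nodes != net_b$n_nodes) stop("networks must share the node set")
  res_a <- spatial_metric(net_a, geom, metric)
  res_b <- spatial_metric(net_b, geom, metric)
  if (!res_a$defined || !res_b$defined) {
    stop("metric is undefined on one of the networks (degenerate input)")
  }
  s_a <- coevolution_strengths(net_a)
  s_b <- coevolution_strengths(net_b)
  v <- metric_covariate(geom, net_a$n_nodes, metric)
  observed <- abs(res_a$R - res_b$R)
  null_d <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      swap <- stats::runif(length(s_a)) < 0.5
      sa <- ifelse(swap, s_b, s_a)
      sb <- ifelse(swap, s_a, s_b)
      if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(Inf)
      abs(stats::cor(sa, v) - stats::cor(sb, v))
    }, numeric(1))
  })
  list(statistic = observed, R_a = res_a$R, R_b = res_b$R,
       p = (1 + sum(null_d >= observed)) / (1 + n_permutations),
       metric = metric)
}
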