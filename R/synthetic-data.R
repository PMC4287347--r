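#' Default task ladder for synthetic designs
#'
#' Four tasks with the sampling periods of a typical multi-task protocol:
#' rest and attention at TR 2 s, word and face memory at TR 2.5 s, so the
#' unequal samples-per-window case (30 vs 24 samples per 60 s window) is
#' exercised by default.
#'
#' @param n_windows windows per task (recycled over the four tasks).
#' @return data frame with columns `task`, `tr`, `n_windows`.
#' @export
default_tasks <- function(n_windows = 12) {
  data.frame(task = c("rest", "attention", "word", "face"),
             tr = c(2, 2, 2.5, 2.5),
             n_windows = as.integer(rep_len(n_windows, 4)))
}

#' Planted edge group
#'
#' @param pairs two-column matrix (or data frame) of node pairs, 1-based.
#' @param amplitude target co-evolution amplitude in `[0, 1]`: the scale of
#'   the shared latent trajectory injected into member edges.
#' @param task optional task restriction: the shared trajectory is injected
#'   only into that task's windows, members are independent elsewhere.
#' @param baseline mean edge-weight level while the group is active; a
#'   nonzero baseline plants a between-task level shift (relevant for the
#'   within-task null model).
#' @return object of class `planted_group`.
#' @export
planted_group <- function(pairs, amplitude, task = NULL, baseline = 0) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 1)
  if (any(pairs[, 1] == pairs[, 2])) stop("node pairs must be distinct nodes")
  if (!(amplitude >= 0 && amplitude <= 1)) stop("amplitude must lie in [0, 1]")
  stopifnot(abs(baseline) <= 1)
  structure(list(pairs = cbind(pmin(pairs[, 1], pairs[, 2]),
                               pmax(pairs[, 1], pairs[, 2])),
                 amplitude = amplitude,
                 task = if (is.null(task)) NULL else as.character(task),
                 baseline = baseline),
            class = "planted_group")
}

#' Planted co-evolution design
#'
#' Describes a synthetic multi-task experiment: the node count, the task
#' ladder (name, TR, window count), the planted edge groups whose weight
#' series co-evolve, and the noise level.
#'
#' @param n_nodes number of regions.
#' @param tasks data frame with columns `task`, `tr` (seconds), `n_windows`
#'   (each >= 2); default [default_tasks()].
#' @param groups list of [planted_group()] objects with disjoint member
#'   edges; node indices must lie in `[1, n_nodes]`.
#' @param noise_sd standard deviation of the independent noise on every
#'   edge (edge-level) or region carrier (region-level).
#' @param seed integer seed; identical designs and seeds give identical
#'   data.
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_nodes, tasks = default_tasks(), groups = list(),
                           noise_sd = 0.1, seed = 1L) {
  stopifnot(n_nodes >= 2, noise_sd >= 0, length(seed) == 1)
  tasks <- as.data.frame(tasks)
  stopifnot(all(c("task", "tr", "n_windows") %in% names(tasks)),
            nrow(tasks) >= 1, all(tasks$tr > 0), all(tasks$n_windows >= 2),
            !anyDuplicated(tasks$task))
  seen <- integer(0)
  for (g in groups) {
    if (!inherits(g, "planted_group")) stop("groups must be planted_group objects")
    if (any(g$pairs > n_nodes) || any(g$pairs < 1)) {
      stop("group references a node outside [1, n_nodes]")
    }
    if (!is.null(g$task) && !(g$task %in% tasks$task)) {
      stop(sprintf("group restricted to unknown task '%s'", g$task))
    }
    idx <- pair_to_edge(g$pairs[, 1], g$pairs[, 2], n_nodes)
    if (any(idx %in% seen)) stop("planted groups must not share member edges")
    seen <- c(seen, idx)
  }
  structure(list(n_nodes = as.integer(n_nodes), tasks = tasks,
                 groups = groups, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_design")
}

# Smooth latent trajectory in (-1, 1): tanh of a standardized Gaussian
# random walk. Standardizing before the squash keeps the trajectory away
# from saturation, so it always retains enough variance across windows to
# induce detectable co-evolution.
latent_trajectory <- function(n_windows) {
  rw <- cumsum(stats::rnorm(n_windows))
  rw <- (rw - mean(rw)) / max(stats::sd(rw), .Machine$double.eps)
  tanh(rw)
}

# One latent trajectory per group, generated on the group's active windows
# (so a task-restricted group has full trajectory variance inside its
# task) and decorrelated across groups. Independent random walks show
# large spurious sample correlations over a few dozen windows, which would
# merge distinct planted groups; projecting each trajectory off the
# earlier ones over their shared active windows (then restoring its scale)
# keeps the planted groups separable while staying smooth. Entries outside
# a group's active windows are zero.
group_latents <- function(active_list, n_windows) {
  n_groups <- length(active_list)
  latent <- matrix(0, n_groups, max(n_windows, 1))
  for (g in seq_len(n_groups)) {
    latent[g, active_list[[g]]] <- latent_trajectory(length(active_list[[g]]))
  }
  if (n_groups >= 2) {
    for (g in 2:n_groups) {
      act <- active_list[[g]]
      scale0 <- stats::sd(latent[g, act])
      for (h in seq_len(g - 1)) {
        ov <- intersect(act, active_list[[h]])
        if (length(ov) < 4) next
        denom <- sum(latent[h, ov]^2)
        if (denom > 0) {
          latent[g, ov] <- latent[g, ov] -
            sum(latent[g, ov] * latent[h, ov]) / denom * latent[h, ov]
        }
      }
      s <- stats::sd(latent[g, act])
      if (s > 0 && scale0 > 0) latent[g, act] <- latent[g, act] * (scale0 / s)
    }
    latent <- pmin(pmax(latent, -1), 1)
  }
  latent
}

design_window_tasks <- function(design) {
  rep(design$tasks$task, design$tasks$n_windows)
}

group_active_windows <- function(group, window_tasks) {
  if (is.null(group$task)) seq_along(window_tasks)
  else which(window_tasks == group$task)
}

#' Generate an edge-level dataset with planted co-evolution structure
#'
#' Member edges of a planted group share a common latent window trajectory
#' scaled by the group amplitude, plus independent Gaussian noise; if the
#' group is task-restricted the trajectory is injected only into that
#' task's windows and members are independent noise elsewhere. Non-member
#' edges are independent noise throughout. Values are clamped to `[-1, 1]`.
#'
#' @param design a [planted_design()].
#' @return list with `ets` (an [edge_ts()]), `group_of_edge` (integer
#'   vector over edges: 0 for background, otherwise the group index) and
#'   `latent` (n_groups x W matrix of latent trajectories).
#' @export
generate_edge_level <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  window_tasks <- design_window_tasks(design)
  n_win <- length(window_tasks)
  n_edges <- edge_count(design$n_nodes)
  n_groups <- length(design$groups)
  group_of_edge <- integer(n_edges)
  with_seed(design$seed, {
    weights <- matrix(stats::rnorm(n_edges * n_win, sd = design$noise_sd),
                      n_edges, n_win)
    active_list <- lapply(design$groups, group_active_windows, window_tasks)
    latent <- group_latents(active_list, n_win)
    for (g in seq_len(n_groups)) {
      grp <- design$groups[[g]]
      active <- group_active_windows(grp, window_tasks)
      rows <- pair_to_edge(grp$pairs[, 1], grp$pairs[, 2], design$n_nodes)
      group_of_edge[rows] <- g
      signal <- grp$baseline + grp$amplitude * latent[g, active]
      weights[rows, active] <- weights[rows, active] +
        matrix(signal, nrow = length(rows), ncol = length(active), byrow = TRUE)
    }
    weights <- pmin(pmax(weights, -1), 1)
    list(ets = edge_ts(weights, design$n_nodes, window_tasks),
         group_of_edge = group_of_edge,
         latent = latent)
  })
}

# Band-limited unit-variance carrier: random-phase sinusoids in the
# 0.06-0.125 Hz band, so the band-pass filter of signal_prep passes it.
band_limited_carrier <- function(n_samples, tr, low = 0.065, high = 0.120,
                                 n_components = 8) {
  t_sec <- (seq_len(n_samples) - 1) * tr
  freqs <- stats::runif(n_components, low, high)
  phases <- stats::runif(n_components, 0, 2 * pi)
  s <- rowSums(sin(outer(t_sec, 2 * pi * freqs) +
                     matrix(phases, n_samples, n_components, byrow = TRUE)))
  s / stats::sd(s)
}

#' Generate region-level runs with planted co-evolution structure
#'
#' Emits one [region_run()] per task. Each planted node pair carries its own
#' band-limited shared signal; within every window the pair's nodes mix that
#' signal with weight `amplitude * (0.6 + 0.4 * latent_w)`, so the windowed
#' Pearson edge weight of the pair rises and falls with the group's latent
#' trajectory and all of a group's edges co-evolve, while node pairs
#' spanning two different planted pairs stay uncorrelated. All other
#' regional activity is independent band-limited noise.
#'
#' @param design a [planted_design()].
#' @param window_seconds window length used to lay out the planted windows
#'   (the region series has `floor(window_seconds / tr) * n_windows` samples
#'   per task).
#' @param subject_id subject identifier stamped on the runs.
#' @param mean_fd mean framewise displacement of the simulated motion
#'   traces attached to each run.
#' @return list with `runs` (list of [region_run()]), `group_of_edge`,
#'   `latent` (n_groups x total-windows matrix) and `window_tasks`.
#' @export
generate_region_level <- function(design, window_seconds = 60,
                                  subject_id = "sim01", mean_fd = 0.1) {
  stopifnot(inherits(design, "planted_design"))
  window_tasks <- design_window_tasks(design)
  n_groups <- length(design$groups)
  with_seed(design$seed, {
    active_list <- lapply(design$groups, group_active_windows, window_tasks)
    latent <- group_latents(active_list, length(window_tasks))
    group_of_edge <- integer(edge_count(design$n_nodes))
    runs <- vector("list", nrow(design$tasks))
    offset <- 0L
    for (k in seq_len(nrow(design$tasks))) {
      task <- design$tasks$task[k]
      tr <- design$tasks$tr[k]
      n_win <- design$tasks$n_windows[k]
      len <- floor(window_seconds / tr)
      if (len < 3) stop(sprintf("task '%s': window of %d samples is too short",
                                task, len))
      n_samples <- len * n_win
      data <- t(vapply(seq_len(design$n_nodes), function(i) {
        band_limited_carrier(n_samples, tr)
      }, numeric(n_samples)))
      member <- logical(design$n_nodes)
      for (g in seq_len(n_groups)) {
        grp <- design$groups[[g]]
        rows <- pair_to_edge(grp$pairs[, 1], grp$pairs[, 2], design$n_nodes)
        group_of_edge[rows] <- g
        member[unique(as.vector(grp$pairs))] <- TRUE
      }
      # members keep only noise_sd of their own activity; planted carriers
      # are added on top, window by window
      data[member, ] <- data[member, , drop = FALSE] * design$noise_sd
      for (g in seq_len(n_groups)) {
        grp <- design$groups[[g]]
        active_local <- if (is.null(grp$task) || grp$task == task)
          seq_len(n_win) else integer(0)
        if (length(active_local) == 0) next
        mix <- grp$amplitude * (0.6 + 0.4 * latent[g, offset + active_local])
        for (p in seq_len(nrow(grp$pairs))) {
          carrier <- band_limited_carrier(n_samples, tr)
          for (wi in seq_along(active_local)) {
            cols <- ((active_local[wi] - 1L) * len + 1L):(active_local[wi] * len)
            add <- mix[wi] * carrier[cols]
            data[grp$pairs[p, 1], cols] <- data[grp$pairs[p, 1], cols] + add
            data[grp$pairs[p, 2], cols] <- data[grp$pairs[p, 2], cols] + add
          }
        }
      }
      fd <- generate_fd_trace(n_samples - 1, mean_fd, seed = NULL)
      runs[[k]] <- region_run(data, tr, task, subject_id = subject_id, fd = fd)
      offset <- offset + n_win
    }
    list(runs = runs, group_of_edge = group_of_edge, latent = latent,
         window_tasks = window_tasks)
  })
}

#' Simulated framewise-displacement trace
#'
#' Nonnegative per-transition displacements rescaled so the sample mean
#' equals `mean_fd` exactly (a zero mean gives an all-zero trace).
#'
#' @param n_samples number of frame transitions (>= 1).
#' @param mean_fd target mean displacement in mm (>= 0).
#' @param seed optional integer seed; `NULL` draws from the current stream.
#' @return numeric vector of length `n_samples`.
#' @export
generate_fd_trace <- function(n_samples, mean_fd, seed = NULL) {
  stopifnot(n_samples >= 1, mean_fd >= 0)
  if (mean_fd == 0) return(numeric(n_samples))
  with_seed(seed, {
    x <- abs(stats::rnorm(n_samples, mean = 1, sd = 0.4))
    x * mean_fd / mean(x)
  })
}

#' Simulated per-subject region-size table over two parcellation scales
#'
#' Builds a coarse scale of `n_regions` regions, each split into
#' `children` finer regions carrying a parent pointer, with per-subject
#' voxel counts. Designated outliers receive either a very small mean size
#' or a cross-subject coefficient of variation at a requested level, and
#' optionally a zero-voxel run, to exercise the hybrid-atlas rules.
#'
#' @param n_subjects,n_regions counts (>= 1); `n_regions` is the number of
#'   coarse regions.
#' @param outlier_spec list with optional elements `small` (fine-region
#'   indices given mean size ~30 voxels), `high_cv` (fine-region indices
#'   given relative spread `cv`), `cv` (target CV level, default 0.5), and
#'   `zero` (fine-region indices given zero voxels for subject 1).
#' @param seed integer seed.
#' @param children fine regions per coarse region.
#' @param base_cv relative cross-subject spread of unremarkable regions.
#' @return data frame with columns `region`, `scale` (`"coarse"` or
#'   `"fine"`), `parent` (`NA` for coarse), `subject`, `voxels`.
#' @export
generate_region_size_table <- function(n_subjects, n_regions,
                                       outlier_spec = list(), seed = 1L,
                                       children = 2L, base_cv = 0.05) {
  stopifnot(n_subjects >= 1, n_regions >= 1, children >= 1)
  cv_level <- if (is.null(outlier_spec$cv)) 0.5 else outlier_spec$cv
  with_seed(seed, {
    n_fine <- n_regions * children
    fine_region <- paste0("fine_", rep(seq_len(n_regions), each = children),
                          letters[rep(seq_len(children), n_regions)])
    parent <- paste0("coarse_", rep(seq_len(n_regions), each = children))
    means <- stats::runif(n_fine, 250, 600)
    rel_sd <- rep(base_cv, n_fine)
    if (!is.null(outlier_spec$small)) means[outlier_spec$small] <- 30
    if (!is.null(outlier_spec$high_cv)) rel_sd[outlier_spec$high_cv] <- cv_level
    voxels <- matrix(0L, n_fine, n_subjects)
    for (r in seq_len(n_fine)) {
      voxels[r, ] <- pmax(1L, as.integer(round(
        means[r] * (1 + stats::rnorm(n_subjects, sd = rel_sd[r])))))
    }
    if (!is.null(outlier_spec$zero)) voxels[outlier_spec$zero, 1] <- 0L
    fine <- data.frame(region = rep(fine_region, n_subjects),
                       scale = "fine",
                       parent = rep(parent, n_subjects),
                       subject = rep(seq_len(n_subjects), each = n_fine),
                       voxels = as.integer(voxels[cbind(
                         rep(seq_len(n_fine), n_subjects),
                         rep(seq_len(n_subjects), each = n_fine))]))
    coarse_sizes <- rowsum(fine$voxels, paste(fine$parent, fine$subject))
    key <- expand.grid(parent = paste0("coarse_", seq_len(n_regions)),
                       subject = seq_len(n_subjects),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    coarse <- data.frame(region = key$parent, scale = "coarse",
                         parent = NA_character_, subject = key$subject,
                         voxels = as.integer(coarse_sizes[
                           paste(key$parent, key$subject), 1]))
    out <- rbind(fine, coarse)
    rownames(out) <- NULL
    out
  })
}
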