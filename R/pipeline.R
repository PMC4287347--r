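pipeline_defaults <- function() {
  list(
    n_subjects = 1L,
    simulate = list(n_nodes = 12L, noise_sd = 0.2, n_windows = 8L,
                    groups = list(), mean_fd = 0.1),
    band = list(low = 0.06, high = 0.125, order = 4L),
    window = list(mode = "duration", window_seconds = 60,
                  window_points = NULL),
    motion_threshold = 0.25,
    fdr = list(q = 0.05, alternative = "two.sided"),
    classify = list(enabled = TRUE, alpha = 0.05, n_permutations = 200L),
    metrics = list(enabled = TRUE, n_permutations = 200L),
    nulls = list()
  )
}

merge_config <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Assemble and validate a pipeline configuration
#'
#' Unspecified fields take the package defaults; the master `seed` is
#' mandatory. Validation failures are reported with the offending field
#' path.
#'
#' @param config named list of overrides, or a path to a YAML/JSON file.
#' @return validated configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  full <- merge_config(pipeline_defaults(), config)
  fail <- function(field, msg) stop(sprintf("config field '%s': %s", field, msg),
                                    call. = FALSE)
  if (is.null(full$seed)) fail("seed", "a master seed is mandatory")
  if (!is.numeric(full$seed) || length(full$seed) != 1) {
    fail("seed", "must be a single integer")
  }
  q <- full$fdr$q
  if (!is.numeric(q) || q <= 0 || q >= 1) fail("fdr.q", "must lie in (0, 1)")
  if (!full$fdr$alternative %in% c("two.sided", "greater")) {
    fail("fdr.alternative", "must be 'two.sided' or 'greater'")
  }
  if (full$band$low <= 0 || full$band$high <= full$band$low) {
    fail("band", "needs 0 < low < high")
  }
  if (!full$window$mode %in% c("duration", "points")) {
    fail("window.mode", "must be 'duration' or 'points'")
  }
  if (full$motion_threshold <= 0) fail("motion_threshold", "must be positive")
  a <- full$classify$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1) {
    fail("classify.alpha", "must lie in (0, 1)")
  }
  if (full$classify$n_permutations < 1) {
    fail("classify.n_permutations", "must be >= 1")
  }
  if (full$n_subjects < 1) fail("n_subjects", "must be >= 1")
  for (kind in full$nulls) {
    if (!kind %in% c("overall", "within-task")) {
      fail("nulls", sprintf("unknown null kind '%s'", kind))
    }
  }
  full$seed <- as.integer(full$seed)
  structure(full, class = c("pipeline_config", "list"))
}

config_design <- function(config, subject_seed) {
  sim <- config$simulate
  tasks <- if (is.null(sim$tasks)) default_tasks(sim$n_windows)
           else as.data.frame(sim$tasks)
  groups <- lapply(sim$groups, function(g) {
    if (inherits(g, "planted_group")) return(g)
    planted_group(do.call(rbind, lapply(g$pairs, as.integer)),
                  amplitude = g$amplitude,
                  task = g$task,
                  baseline = if (is.null(g$baseline)) 0 else g$baseline)
  })
  planted_design(sim$n_nodes, tasks = tasks, groups = groups,
                 noise_sd = sim$noise_sd, seed = subject_seed)
}

load_subject_runs <- function(config, s) {
  if (!is.null(config$input)) {
    prefixes <- config$input[[s]]
    list(runs = lapply(prefixes, read_region_run), truth = NULL)
  } else {
    sim <- generate_region_level(
      config_design(config, derive_seed(config$seed, paste0("subject-", s))),
      window_seconds = if (config$window$mode == "duration")
        config$window$window_seconds else 60,
      subject_id = sprintf("sim%02d", s),
      mean_fd = config$simulate$mean_fd)
    list(runs = sim$runs, truth = sim)
  }
}

#' Run the full hypergraph co-evolution pipeline
#'
#' Executes, per subject: motion exclusion, band-pass filtering, windowing,
#' edge time series extraction, edge-edge correlation, FDR binarization,
#' hyperedge extraction, diagnostics, optional task-specificity
#' classification; then across subjects: co-evolution network, threshold
#' bands, spatial metrics, and any requested null models. Subjects are
#' simulated from `config$simulate` unless `config$input` names run files.
#' Every artifact is written under `out_dir`, with a metadata block (config
#' echo, config hash, seed, package version); re-running with the same
#' config reproduces all outputs bit-for-bit.
#'
#' @param config a [pipeline_config()] (or list / file path coercible to
#'   one).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the per-subject hypergraphs, the
#'   co-evolution network, diagnostics, task-specificity results, metric
#'   results and null summaries.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  band <- bandpass_spec(config$band$low, config$band$high, config$band$order)
  window <- windowing_spec(config$window$mode,
                           window_seconds = config$window$window_seconds,
                           window_points = config$window$window_points)
  hypergraphs <- list()
  specificity <- list()
  nulls <- list()
  excluded_runs <- character(0)
  ets_list <- list()
  for (s in seq_len(config$n_subjects)) {
    loaded <- load_subject_runs(config, s)
    qc <- exclude_high_motion(loaded$runs, threshold = config$motion_threshold)
    excluded_runs <- c(excluded_runs, qc$excluded)
    if (length(qc$kept) == 0) next
    ets <- edge_ts_from_runs(qc$kept, window = window, band = band)
    ets_list[[s]] <- ets
    write_edge_ts(ets, file.path(out_dir, sprintf("edge_ts_s%02d.csv", s)))
    eec <- edge_edge_correlation(ets, alternative = config$fdr$alternative)
    bin <- fdr_binarize(eec, q = config$fdr$q)
    hg <- extract_hyperedges(bin, ets$n_nodes,
                             subject_id = qc$kept[[1]]$subject_id)
    hypergraphs[[length(hypergraphs) + 1]] <- hg
    write_hypergraph(hg, file.path(out_dir, sprintf("hypergraph_s%02d.json", s)))
    if (isTRUE(config$classify$enabled) &&
        length(unique(ets$window_tasks)) >= 2) {
      cls <- classify_hyperedges(
        hg, ets, alpha = config$classify$alpha,
        n_permutations = config$classify$n_permutations,
        seed = derive_seed(config$seed, paste0("classify-", s)))
      specificity[[length(specificity) + 1]] <- cls
      utils::write.csv(cbind(cls$table,
                             label = cls$labels[cls$table$hyperedge]),
                       file.path(out_dir, sprintf("task_specificity_s%02d.csv", s)),
                       row.names = FALSE)
    }
    for (kind in config$nulls) {
      nr <- run_null(ets, kind = kind,
                     seed = derive_seed(config$seed,
                                        paste0("null-", kind, "-", s)),
                     q = config$fdr$q, alternative = config$fdr$alternative)
      nulls[[length(nulls) + 1]] <- nr
      jsonlite::write_json(
        list(kind = nr$kind, subject = s, seed = nr$seed, q = nr$q,
             n_hyperedges = length(nr$hypergraph$hyperedges),
             sizes = hyperedge_size(nr$hypergraph)),
        file.path(out_dir, sprintf("null_%s_s%02d.json",
                                   gsub("-", "_", kind), s)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  if (length(hypergraphs) == 0) stop("all runs were excluded; nothing to analyze")
  utils::write.csv(size_distribution(hypergraphs),
                   file.path(out_dir, "size_distribution.csv"),
                   row.names = FALSE)
  n_nodes <- hypergraphs[[1]]$n_nodes
  utils::write.csv(data.frame(node = seq_len(n_nodes),
                              degree = hyperedge_node_degree(hypergraphs)),
                   file.path(out_dir, "hyperedge_node_degree.csv"),
                   row.names = FALSE)
  net <- coevolution_matrix(hypergraphs, label = "all")
  write_coevolution(net, file.path(out_dir, "coevolution_all.csv"),
                    graphml_path = file.path(out_dir, "coevolution_all.graphml"))
  utils::write.csv(threshold_bands(net),
                   file.path(out_dir, "coevolution_bands.csv"),
                   row.names = FALSE)
  metric_rows <- NULL
  geom <- NULL
  if (isTRUE(config$metrics$enabled)) {
    geom <- if (!is.null(config$geometry)) {
      read_node_geometry(config$geometry)
    } else {
      with_seed(derive_seed(config$seed, "geometry"), {
        node_geometry(stats::runif(n_nodes, -70, 70),
                      stats::runif(n_nodes, -100, 70),
                      stats::runif(n_nodes, -50, 80))
      })
    }
    for (metric in c("length-strength", "position-strength")) {
      res <- tryCatch(
        metric_significance(net, geom, metric = metric,
                            n_permutations = config$metrics$n_permutations,
                            seed = derive_seed(config$seed,
                                               paste0("metric-", metric))),
        error = function(e) NULL)
      if (!is.null(res)) {
        metric_rows <- rbind(metric_rows,
                             data.frame(network = net$label, metric = metric,
                                        R = res$R, p = res$p))
      }
    }
    if (!is.null(metric_rows)) {
      utils::write.csv(metric_rows, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    }
  }
  meta <- list(config = unclass(config),
               config_hash = config_hash(unclass(config)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("hypercoev")),
               excluded_runs = excluded_runs,
               n_subjects_analyzed = length(hypergraphs))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(hypergraphs = hypergraphs, edge_ts = ets_list,
                 coevolution = net, specificity = specificity,
                 nulls = nulls, metrics = metric_rows, geometry = geom,
                 excluded_runs = excluded_runs, metadata = meta))
}
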