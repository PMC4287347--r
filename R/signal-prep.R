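#' One subject/task run of region-level signal
#'
#' @param data region x sample numeric matrix (one row per region; values are
#'   the mean signal of the region at each acquisition).
#' @param sampling_period sampling period (TR) in seconds.
#' @param task task label of the run.
#' @param subject_id subject identifier.
#' @param fd optional per-transition framewise displacement trace in mm,
#'   length `ncol(data) - 1`.
#' @return object of class `region_run`.
#' @export
region_run <- function(data, sampling_period, task,
                       subject_id = NA_character_, fd = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("run data must not contain missing values")
  stopifnot(sampling_period > 0)
  if (!is.null(fd)) {
    if (length(fd) != ncol(data) - 1) {
      stop("fd must have one value per frame transition (samples - 1)")
    }
    if (any(fd < 0)) stop("framewise displacement must be nonnegative")
  }
  structure(list(subject_id = as.character(subject_id),
                 task = as.character(task),
                 sampling_period = as.numeric(sampling_period),
                 data = data,
                 fd = fd),
            class = "region_run")
}

#' @export
print.region_run <- function(x, ...) {
  cat(sprintf("<region_run> subject %s, task %s: %d regions x %d samples, TR %g s%s\n",
              x$subject_id, x$task, nrow(x$data), ncol(x$data),
              x$sampling_period,
              if (is.null(x$fd)) "" else sprintf(", mean FD %.3f mm", mean(x$fd))))
  invisible(x)
}

run_label <- function(run) paste(run$subject_id, run$task, sep = "/")

#' Exclude runs with excessive head motion
#'
#' A run is kept iff its mean framewise displacement is strictly below the
#' threshold (default 0.25 mm per frame).
#'
#' @param runs list of [region_run()] objects, each with an `fd` trace.
#' @param threshold mean-FD exclusion threshold in mm.
#' @return list with `kept` (runs, input order preserved) and `excluded`
#'   (character labels `subject/task` of dropped runs).
#' @export
exclude_high_motion <- function(runs, threshold = 0.25) {
  stopifnot(is.list(runs), threshold > 0)
  for (r in runs) {
    if (!inherits(r, "region_run")) stop("runs must be region_run objects")
    if (is.null(r$fd)) {
      stop(sprintf("run %s has no framewise-displacement trace", run_label(r)))
    }
  }
  keep <- vapply(runs, function(r) mean(r$fd) < threshold, logical(1))
  list(kept = runs[keep],
       excluded = vapply(runs[!keep], run_label, character(1)))
}

#' Band-pass specification
#'
#' Defaults isolate the 0.06-0.125 Hz band of the BOLD signal.
#'
#' @param low,high band edges in Hz; `0 < low < high`.
#' @param order Butterworth filter order.
#' @export
bandpass_spec <- function(low = 0.06, high = 0.125, order = 4) {
  stopifnot(low > 0, high > low, order >= 1, order == round(order))
  structure(list(low = low, high = high, order = as.integer(order)),
            class = "bandpass_spec")
}

#' Zero-phase Butterworth band-pass filter of a run
#'
#' Each region's time series is filtered independently with a Butterworth
#' band-pass applied forward and backward ([signal::filtfilt()]), so the
#' output is zero-phase and no inter-region lag is introduced.
#'
#' @param run a [region_run()].
#' @param spec a [bandpass_spec()]; the high edge must lie below the run's
#'   Nyquist frequency `1 / (2 * TR)`.
#' @return the run with filtered `data` (same shape).
#' @export
bandpass <- function(run, spec = bandpass_spec()) {
  stopifnot(inherits(run, "region_run"), inherits(spec, "bandpass_spec"))
  nyquist <- 1 / (2 * run$sampling_period)
  if (spec$high >= nyquist) {
    stop(sprintf(
      "band edge %g Hz is at or above the Nyquist frequency %g Hz (TR %g s)",
      spec$high, nyquist, run$sampling_period))
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / nyquist,
                       type = "pass")
  filt <- t(apply(run$data, 1, function(x) signal::filtfilt(bf, x)))
  run$data <- filt
  run
}

#' Windowing specification
#'
#' Duration mode cuts windows of a fixed length in seconds (default 60 s, so
#' 30 samples at TR 2 s and 24 at TR 2.5 s); point-count mode holds the
#' number of samples per window constant across runs with different TRs.
#'
#' @param mode `"duration"` or `"points"`.
#' @param window_seconds window length in seconds (duration mode).
#' @param window_points samples per window (points mode).
#' @export
windowing_spec <- function(mode = c("duration", "points"),
                           window_seconds = 60, window_points = NULL) {
  mode <- match.arg(mode)
  if (mode == "duration") {
    stopifnot(is.numeric(window_seconds), window_seconds > 0)
  } else {
    stopifnot(!is.null(window_points), window_points >= 3,
              window_points == round(window_points))
  }
  structure(list(mode = mode, window_seconds = window_seconds,
                 window_points = if (is.null(window_points)) NULL
                                 else as.integer(window_points)),
            class = "windowing_spec")
}

window_length_samples <- function(run, spec) {
  if (spec$mode == "duration") {
    floor(spec$window_seconds / run$sampling_period)
  } else {
    spec$window_points
  }
}

#' Segment a run into contiguous, non-overlapping windows
#'
#' Windows never straddle runs; trailing samples short of a full window are
#' discarded (a short window would bias the Pearson estimate). Every window
#' inherits the run's task label.
#'
#' @param run a [region_run()].
#' @param spec a [windowing_spec()].
#' @return list of windows, each `list(data = region x sample matrix,
#'   task = label)`.
#' @export
segment_windows <- function(run, spec = windowing_spec()) {
  stopifnot(inherits(run, "region_run"), inherits(spec, "windowing_spec"))
  len <- window_length_samples(run, spec)
  if (len < 3) {
    stop(sprintf("run %s: window of %d samples is too short (need >= 3)",
                 run_label(run), len))
  }
  n_win <- floor(ncol(run$data) / len)
  if (n_win < 1) {
    stop(sprintf("run %s: %d samples do not fill one window of %d samples",
                 run_label(run), ncol(run$data), len))
  }
  lapply(seq_len(n_win), function(w) {
    cols <- ((w - 1L) * len + 1L):(w * len)
    list(data = run$data[, cols, drop = FALSE], task = run$task)
  })
}
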