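#' Coefficient of variation of a region's size across subjects
#'
#' Sample (n - 1) standard deviation divided by the mean.
#'
#' @param sizes per-subject sizes of one region (length >= 2, positive
#'   mean).
#' @return sd / mean.
#' @export
coefficient_of_variation <- function(sizes) {
  stopifnot(length(sizes) >= 2, all(is.finite(sizes)))
  m <- mean(sizes)
  if (m == 0) stop("coefficient of variation is undefined for mean 0")
  stats::sd(sizes) / m
}

# mean over subjects of the across-region CV of sizes within that subject
within_subject_cv <- function(size_matrix) {
  if (nrow(size_matrix) < 2) return(0)
  mean(apply(size_matrix, 2, function(x) stats::sd(x) / mean(x)))
}

#' Iterative hybrid-atlas refinement
#'
#' Harmonizes region sizes across a cohort by working on the finest
#' parcellation scale: regions whose mean size falls below the
#' `size_percentile` of their scale's mean sizes (threshold frozen from the
#' input table), or whose cross-subject coefficient of variation exceeds
#' `cv_threshold`, are tentatively merged with their sibling regions under
#' the same coarser-scale parent. A merge is retained iff it strictly
#' improves one variability measure relative to the flagged region — the
#' inter-subject CV, or the mean within-subject size variability of the
#' working set — without worsening the other; the typical fix this accepts
#' is a parcel boundary that wanders between two sibling regions across
#' subjects, making their sizes anti-correlated so the merged region is
#' stable. Rejected merges exclude the offending region. Regions with a
#' zero-voxel subject entry are excluded up front (no data acquired), and
#' flagged regions with no merge partner are excluded with reason
#' `high-cv` (CV flag) or `rejected-merge` (size flag).
#'
#' @param table data frame with columns `region`, `scale`, `parent`
#'   (`NA` on the coarsest scale), `subject`, `voxels`, covering at least
#'   two scales (see [generate_region_size_table()]).
#' @param cv_threshold inter-subject CV above which a region is flagged.
#' @param size_percentile percentile (0-100) of per-scale mean sizes below
#'   which a region is flagged as too small.
#' @return object of class `hybrid_atlas`: `accepted` (data frame:
#'   `region`, `scale`, `provenance` in `{original, merged}`, `members`
#'   comma-joined fine regions, `mean_size`, `cv`), `excluded` (data
#'   frame: `region`, `reason` in `{no-data, high-cv, rejected-merge}`,
#'   `members`), and `n_iterations`.
#' @export
refine_atlas <- function(table, cv_threshold = 0.30, size_percentile = 25) {
  table <- as.data.frame(table)
  stopifnot(all(c("region", "scale", "parent", "subject", "voxels") %in%
                  names(table)),
            cv_threshold > 0, size_percentile > 0, size_percentile < 100)
  if (length(unique(table$scale)) < 2) stop("need at least 2 parcellation scales")
  fine_rows <- table[!is.na(table$parent), , drop = FALSE]
  if (nrow(fine_rows) == 0) stop("no scale carries parent pointers")
  subjects <- sort(unique(table$subject))
  if (length(subjects) < 2) stop("need at least 2 subjects")
  fine_ids <- unique(fine_rows$region)
  sizes <- t(vapply(fine_ids, function(r) {
    x <- fine_rows[fine_rows$region == r, ]
    x$voxels[match(subjects, x$subject)]
  }, numeric(length(subjects))))
  rownames(sizes) <- fine_ids
  parent_of <- fine_rows$parent[match(fine_ids, fine_rows$region)]
  names(parent_of) <- fine_ids
  fine_scale <- fine_rows$scale[1]
  coarse_rows <- table[is.na(table$parent), , drop = FALSE]

  # frozen per-scale small-size thresholds from the input table
  fine_means <- rowMeans(sizes)
  size_thr <- list()
  size_thr[[fine_scale]] <- stats::quantile(fine_means, size_percentile / 100,
                                            names = FALSE)
  if (nrow(coarse_rows) > 0) {
    cm <- tapply(coarse_rows$voxels, coarse_rows$region, mean)
    size_thr[[coarse_rows$scale[1]]] <-
      stats::quantile(as.numeric(cm), size_percentile / 100, names = FALSE)
  }

  # working state: one record per accepted candidate region
  working <- lapply(fine_ids, function(r) {
    list(region = r, scale = fine_scale, parent = parent_of[[r]],
         provenance = "original", members = r, sizes = sizes[r, ])
  })
  names(working) <- fine_ids
  excluded <- list()
  exclude <- function(rec, reason) {
    excluded[[length(excluded) + 1]] <<-
      data.frame(region = rec$region, reason = reason,
                 members = paste(rec$members, collapse = ","))
    working[[rec$region]] <<- NULL
  }

  # no-data rule: any zero-voxel subject entry excludes the region outright
  for (r in names(working)) {
    if (any(working[[r]]$sizes == 0)) exclude(working[[r]], "no-data")
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10L * length(fine_ids) + 10L) {
      stop("refine_atlas failed to terminate")  # unreachable guard
    }
    if (length(working) == 0) break
    cvs <- vapply(working, function(rec) coefficient_of_variation(rec$sizes),
                  numeric(1))
    means <- vapply(working, function(rec) mean(rec$sizes), numeric(1))
    scales <- vapply(working, function(rec) rec$scale, character(1))
    thr <- vapply(scales, function(s) {
      if (is.null(size_thr[[s]])) -Inf else size_thr[[s]]
    }, numeric(1))
    cv_flag <- cvs > cv_threshold
    size_flag <- means < thr
    flagged <- which(cv_flag | size_flag)
    if (length(flagged) == 0) break
    # process the worst offender first: highest CV, then smallest size
    pick <- flagged[order(-cvs[flagged], means[flagged])][1]
    rec <- working[[pick]]
    flagged_by_cv <- cv_flag[pick]
    sibs <- Filter(function(w) !identical(w$region, rec$region) &&
                     identical(w$parent, rec$parent) && !is.na(w$parent),
                   working)
    if (is.na(rec$parent) || length(sibs) == 0) {
      exclude(rec, if (flagged_by_cv) "high-cv" else "rejected-merge")
      next
    }
    merged_sizes <- rec$sizes
    for (s in sibs) merged_sizes <- merged_sizes + s$sizes
    size_mat_before <- t(vapply(working, function(w) w$sizes,
                                numeric(length(subjects))))
    keep <- setdiff(names(working), c(rec$region,
                                      vapply(sibs, `[[`, character(1), "region")))
    size_mat_after <- rbind(
      if (length(keep) > 0) size_mat_before[keep, , drop = FALSE],
      merged = merged_sizes)
    within_before <- within_subject_cv(size_mat_before)
    within_after <- within_subject_cv(size_mat_after)
    merged_cv <- coefficient_of_variation(merged_sizes)
    # retained iff one variability measure strictly improves on the flagged
    # region while the other does not get worse
    ok <- (merged_cv < cvs[pick] - 1e-12 &&
             within_after <= within_before + 1e-12) ||
          (within_after < within_before - 1e-12 &&
             merged_cv <= cvs[pick] + 1e-12)
    if (ok) {
      coarse_scale <- setdiff(unique(table$scale), fine_scale)[1]
      merged_rec <- list(
        region = rec$parent, scale = coarse_scale, parent = NA_character_,
        provenance = "merged",
        members = c(rec$members, unlist(lapply(sibs, `[[`, "members"),
                                        use.names = FALSE)),
        sizes = merged_sizes)
      for (s in sibs) working[[s$region]] <- NULL
      working[[rec$region]] <- NULL
      working[[merged_rec$region]] <- merged_rec
    } else {
      exclude(rec, "rejected-merge")
    }
  }

  accepted <- if (length(working) == 0) {
    data.frame(region = character(0), scale = character(0),
               provenance = character(0), members = character(0),
               mean_size = numeric(0), cv = numeric(0))
  } else {
    data.frame(
      region = vapply(working, `[[`, character(1), "region"),
      scale = vapply(working, `[[`, character(1), "scale"),
      provenance = vapply(working, `[[`, character(1), "provenance"),
      members = vapply(working, function(w) paste(w$members, collapse = ","),
                       character(1)),
      mean_size = vapply(working, function(w) mean(w$sizes), numeric(1)),
      cv = vapply(working, function(w) coefficient_of_variation(w$sizes),
                  numeric(1)),
      row.names = NULL)
  }
  excluded <- if (length(excluded) == 0) {
    data.frame(region = character(0), reason = character(0),
               members = character(0))
  } else {
    do.call(rbind, excluded)
  }
  structure(list(accepted = accepted, excluded = excluded,
                 n_iterations = iter,
                 cv_threshold = cv_threshold,
                 size_percentile = size_percentile),
            class = "hybrid_atlas")
}

#' @export
print.hybrid_atlas <- function(x, ...) {
  cat(sprintf("<hybrid_atlas> %d accepted (%d merged), %d excluded (%s) after %d iterations\n",
              nrow(x$accepted), sum(x$accepted$provenance == "merged"),
              nrow(x$excluded),
              if (nrow(x$excluded) == 0) "none" else
                paste(names(table(x$excluded$reason)),
                      table(x$excluded$reason), sep = ":", collapse = ", "),
              x$n_iterations))
  invisible(x)
}
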