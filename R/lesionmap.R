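#' Sample tracking seeds from every parcellation region
#'
#' Draws `n_per_roi` seed points uniformly from each ROI's voxels (voxel
#' centers; with replacement when the ROI holds fewer voxels than
#' requested). Empty ROIs are skipped with a warning.
#'
#' @param labels integer-label [volume3d] parcellation.
#' @param n_per_roi seeds per region (default 100, the reference fiber count
#'   per region).
#' @param roi_ids optional subset of label ids (default: all nonzero labels).
#' @param seed integer seed.
#' @return Named list mapping ROI id to an n x 3 matrix of world-mm seeds.
#' @export
seed_rois <- function(labels, n_per_roi = 100, roi_ids = NULL, seed = 1L) {
  n_per_roi <- check_count(n_per_roi, "n_per_roi", min = 1L)
  ids <- roi_ids %||% sort(unique(labels$grid[labels$grid != 0]))
  dims <- dim(labels$grid)
  with_seed(seed, {
    out <- list()
    for (r in ids) {
      vox <- which(labels$grid == r)
      if (!length(vox)) {
        warning("ROI ", r, " is empty; skipped", call. = FALSE)
        next
      }
      pick <- vox[sample.int(length(vox), n_per_roi,
                             replace = length(vox) < n_per_roi)]
      out[[as.character(r)]] <- voxel_to_world(labels, arrayInd(pick, dims) - 1)
    }
    out
  })
}

#' Percentage of blob voxels reached by one region's tracts
#'
#' After eliminating low-probability fibers (visitation probability below
#' `vmap_min`, default 1%, computed within the region's own streamline
#' set), returns `100 * |blob voxels intersected by surviving
#' streamlines| / |blob voxels|`.
#'
#' @param blob binary [volume3d].
#' @param roi_streamlines [streamline_set] seeded in one region for one
#'   subject.
#' @param vmap_min probability floor for the fiber elimination.
#' @return Overlap percent in \[0, 100\]; 0 when no fiber survives.
#' @export
roi_blob_overlap <- function(blob, roi_streamlines, vmap_min = 0.01) {
  vox <- which(blob$grid > 0)
  if (!length(vox)) stop_input("empty blob")
  if (length(roi_streamlines$points) == 0L) return(0)
  vmap <- visitation_map(roi_streamlines, blob)
  surv <- filter_voxel_probability(roi_streamlines, vmap, vmap_min)
  if (length(surv$points) == 0L) return(0)
  visited <- unique(unlist(set_voxels(surv, blob), use.names = FALSE))
  100 * length(intersect(vox, visited)) / length(vox)
}

#' Aggregate per-subject overlap percentages into a lesion-map table
#'
#' Means are taken across subjects per region; regions whose mean exceeds
#' `display_threshold` (strict inequality, default 10%) are flagged for
#' display. The table is sorted by descending mean.
#'
#' @param per_subject_percents named list mapping ROI id to the vector of
#'   per-subject overlap percents.
#' @param display_threshold display cut-off, percent.
#' @return Object of class `lesion_map_table` (a data frame with `roi`,
#'   `mean_percent`, `n_subjects`, `displayed`).
#' @export
aggregate_lesion_map <- function(per_subject_percents, display_threshold = 10) {
  if (!length(per_subject_percents)) stop_input("empty lesion-map input")
  rows <- lapply(names(per_subject_percents), function(r) {
    v <- per_subject_percents[[r]]
    if (!length(v)) stop_input("ROI ", r, " has no subject values")
    if (any(v < 0 | v > 100)) stop_input("overlap percents must lie in [0, 100]")
    data.frame(roi = r, mean_percent = mean(v), n_subjects = length(v))
  })
  out <- do.call(rbind, rows)
  out$displayed <- out$mean_percent > display_threshold
  out <- out[order(-out$mean_percent), , drop = FALSE]
  structure(out, class = c("lesion_map_table", "data.frame"),
            display_threshold = display_threshold)
}

#' @export
print.lesion_map_table <- function(x, ...) {
  cat(sprintf("<lesion_map_table> %d regions, %d displayed (mean overlap > %g%%)\n",
              nrow(x), sum(x$displayed), attr(x, "display_threshold")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' White-matter-to-gray-matter network lesion mapping
#'
#' Identifies the gray-matter regions whose emanating tracts traverse a
#' statistical blob: for each subject and each parcellation region,
#' `n_per_roi` fibers are tracked from the region, low-probability fibers
#' (below `vmap_min`) are eliminated, and the percentage of blob voxels
#' covered by the surviving fibers is computed; percentages are averaged
#' across subjects per region.
#'
#' @param blob binary [volume3d].
#' @param labels parcellation [volume3d].
#' @param field [orientation_field] to track on.
#' @param subject_ids ids of the subjects to simulate (seed jitter only).
#' @param n_per_roi fibers per region per subject.
#' @param vmap_min fiber-elimination probability floor.
#' @param display_threshold display cut-off, percent.
#' @param step_mm,max_angle_deg tracking parameters.
#' @param seed integer seed.
#' @return A [aggregate_lesion_map()] table.
#' @export
lesion_map <- function(blob, labels, field, subject_ids, n_per_roi = 100,
                       vmap_min = 0.01, display_threshold = 10,
                       step_mm = 0.5, max_angle_deg = 60, seed = 1L) {
  ids <- sort(unique(labels$grid[labels$grid != 0]))
  percents <- stats::setNames(rep(list(numeric(0)), length(ids)), as.character(ids))
  for (s in subject_ids) {
    seeds <- seed_rois(labels, n_per_roi = n_per_roi,
                       seed = derive_seed(seed, paste0("lesionmap", s)))
    for (r in names(seeds)) {
      sls <- suppressWarnings(
        track_streamlines(field, seeds[[r]], step_mm = step_mm,
                          max_angle_deg = max_angle_deg, subject = s,
                          seed_label = as.integer(r)))
      percents[[r]] <- c(percents[[r]],
                         if (length(sls$points)) roi_blob_overlap(blob, sls, vmap_min)
                         else 0)
    }
  }
  aggregate_lesion_map(percents, display_threshold)
}
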