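field_dirs_at <- function(field, idx1) {
  d <- dim(field$primary)[1:3]
  pri <- c(field$primary[idx1[1], idx1[2], idx1[3], 1],
           field$primary[idx1[1], idx1[2], idx1[3], 2],
           field$primary[idx1[1], idx1[2], idx1[3], 3])
  sec <- if (!is.null(field$secondary))
    c(field$secondary[idx1[1], idx1[2], idx1[3], 1],
      field$secondary[idx1[1], idx1[2], idx1[3], 2],
      field$secondary[idx1[1], idx1[2], idx1[3], 3]) else c(0, 0, 0)
  list(pri = pri, sec = sec)
}

# Propagate from a point along the field in one direction; returns the
# matrix of points (excluding the start point). `ia` is the precomputed
# 3 x 4 inverse affine (world -> continuous voxel).
propagate <- function(field, ia, p0, dir0, step_mm, cos_max, max_steps) {
  dims <- dim(field$primary)[1:3]
  pts <- matrix(0, max_steps, 3)
  p <- p0; d <- dir0; k <- 0L
  repeat {
    if (k >= max_steps) break
    pn <- p + step_mm * d
    idx <- floor(ia[, 1] * pn[1] + ia[, 2] * pn[2] + ia[, 3] * pn[3] + ia[, 4] + 0.5)
    if (any(idx < 0) || any(idx >= dims)) break
    if (!field$mask[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L]) break
    dirs <- field_dirs_at(field, idx + 1L)
    cp <- sum(d * dirs$pri); cs <- sum(d * dirs$sec)
    if (abs(cp) >= abs(cs)) { dn <- dirs$pri; ca <- cp } else { dn <- dirs$sec; ca <- cs }
    if (sum(dn^2) < 1e-12) break          # null orientation
    if (ca < 0) dn <- -dn                 # antipodal sign continuation
    if (abs(ca) < cos_max) break          # turning angle exceeded
    k <- k + 1L
    pts[k, ] <- pn
    p <- pn; d <- dn
  }
  pts[seq_len(k), , drop = FALSE]
}

#' Deterministic streamline tracking on an orientation field
#'
#' Bidirectional propagation along the voxel-wise orientation field with
#' antipodal-aware sign continuation; tracking stops on mask exit, null
#' orientation, or a per-step turning angle above `max_angle_deg`.
#'
#' @param field an [orientation_field].
#' @param seeds n x 3 matrix of world-mm seed points.
#' @param step_mm step length.
#' @param max_angle_deg maximum per-step turning angle (degrees).
#' @param subject subject id recorded on the streamlines.
#' @param seed_label optional per-seed ROI ids.
#' @param max_steps per-direction step cap.
#' @return A [streamline_set]; seeds at null-orientation or out-of-mask
#'   voxels produce no streamline and are counted in the `n_skipped`
#'   attribute (with a warning).
#' @export
track_streamlines <- function(field, seeds, step_mm = 0.5, max_angle_deg = 60,
                              subject = NA_character_, seed_label = NA_integer_,
                              max_steps = 2000L) {
  check_number(step_mm, "step_mm", 0, Inf, closed_lower = FALSE)
  check_number(max_angle_deg, "max_angle_deg", 0, 180, closed_lower = FALSE)
  seeds <- rbind_pts(seeds)
  seed_label <- rep_len(as.integer(seed_label), nrow(seeds))
  cos_max <- cos(max_angle_deg * pi / 180)
  dims <- dim(field$primary)[1:3]
  ia <- solve(field$affine)[1:3, , drop = FALSE]
  out <- list(); labs <- integer(0)
  skipped <- 0L
  for (i in seq_len(nrow(seeds))) {
    p0 <- seeds[i, ]
    idx <- floor(ia[, 1] * p0[1] + ia[, 2] * p0[2] + ia[, 3] * p0[3] + ia[, 4] + 0.5)
    bad <- any(idx < 0) || any(idx >= dims) ||
      !field$mask[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L]
    if (!bad) {
      d0 <- field_dirs_at(field, idx + 1L)$pri
      bad <- sum(d0^2) < 1e-12
    }
    if (bad) { skipped <- skipped + 1L; next }
    fwd <- propagate(field, ia, p0, d0, step_mm, cos_max, max_steps)
    bwd <- propagate(field, ia, p0, -d0, step_mm, cos_max, max_steps)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, 1, 3), fwd)
    if (nrow(pts) >= 2L) {
      out[[length(out) + 1L]] <- pts
      labs <- c(labs, seed_label[i])
    } else skipped <- skipped + 1L
  }
  if (skipped > 0L)
    warning(sprintf("%d seed(s) produced no streamline", skipped), call. = FALSE)
  sls <- streamline_set(out, subject = subject,
                        seed_label = if (length(labs)) labs else NA_integer_)
  attr(sls, "n_skipped") <- skipped
  sls
}

#' Streamline visitation probability map
#'
#' Per voxel, the fraction of streamlines in the set that intersect it; a
#' streamline crossing a voxel more than once counts once.
#'
#' @param streamlines a [streamline_set].
#' @param ref [volume3d] (or [orientation_field]) supplying grid and affine.
#' @return [volume3d] with values in \[0, 1\].
#' @export
visitation_map <- function(streamlines, ref) {
  if (inherits(ref, "orientation_field"))
    ref <- volume3d(ref$mask + 0, ref$affine, ref$space)
  ns <- length(streamlines$points)
  if (ns == 0L) stop_input("empty streamline set")
  dims <- dim(ref$grid)
  counts <- numeric(prod(dims))
  for (p in streamlines$points) {
    vox <- streamline_voxels(p, ref$affine, dims)
    counts[vox] <- counts[vox] + 1
  }
  volume3d(array(counts / ns, dims), ref$affine, ref$space)
}

#' Remove streamlines traversing low-probability voxels
#'
#' A streamline is eliminated when it intersects at least one voxel whose
#' visitation probability falls below `min_prob` (default 0.1%), the
#' false-positive control used before bundle analysis.
#'
#' @param streamlines a [streamline_set].
#' @param vmap visitation-probability [volume3d] computed from this set (or
#'   a superset).
#' @param min_prob probability floor, in (0, 1).
#' @return Filtered [streamline_set] (always a subset of the input).
#' @export
filter_voxel_probability <- function(streamlines, vmap, min_prob = 0.001) {
  check_number(min_prob, "min_prob", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  dims <- dim(vmap$grid)
  keep <- vapply(streamlines$points, function(p) {
    vox <- streamline_voxels(p, vmap$affine, dims)
    length(vox) == 0L || min(vmap$grid[vox]) >= min_prob
  }, TRUE)
  streamlines[keep]
}

# Maximum turning angle (degrees) between consecutive segments.
max_turn_angle <- function(p) {
  if (nrow(p) < 3L) return(0)
  d <- diff(p)
  d <- d / sqrt(rowSums(d^2))
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  max(acos(pmin(pmax(dots, -1), 1))) * 180 / pi
}

#' Remove high-curvature streamlines
#'
#' Eliminates streamlines whose maximum angle between consecutive segments
#' exceeds `max_turn_deg` (default 70 degrees). Streamlines with fewer than
#' three points have zero curvature and always survive.
#'
#' @param streamlines a [streamline_set].
#' @param max_turn_deg turning-angle threshold in (0, 180).
#' @return Filtered [streamline_set].
#' @export
filter_curvature <- function(streamlines, max_turn_deg = 70) {
  check_number(max_turn_deg, "max_turn_deg", 0, 180,
               closed_lower = FALSE, closed_upper = FALSE)
  keep <- vapply(streamlines$points, function(p) max_turn_angle(p) <= max_turn_deg,
                 TRUE)
  streamlines[keep]
}

# Per-voxel, per-streamline mean local direction (antipodally aligned).
voxel_streamline_dirs <- function(streamlines, ref) {
  dims <- dim(ref$grid)
  recs <- vector("list", length(streamlines$points))
  for (i in seq_along(streamlines$points)) {
    tr <- traverse_polyline(streamlines$points[[i]], ref$affine, dims)
    if (!length(tr$vox)) next
    dirs <- tr$dir[tr$seg, , drop = FALSE]
    # align all segment directions in a voxel to the first one (v == -v)
    o <- order(tr$vox)
    vox <- tr$vox[o]; dirs <- dirs[o, , drop = FALSE]
    grp <- cumsum(c(TRUE, vox[-1] != vox[-length(vox)]))
    agg <- rowsum(dirs * sign_align(dirs, grp), grp)
    nrm <- sqrt(rowSums(agg^2)); nrm[nrm == 0] <- 1
    recs[[i]] <- list(vox = vox[!duplicated(grp)], dir = agg / nrm, sl = i)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  vox <- unlist(lapply(recs, `[[`, "vox"), use.names = FALSE)
  sl <- unlist(lapply(recs, function(r) rep.int(r$sl, length(r$vox))), use.names = FALSE)
  dir <- do.call(rbind, lapply(recs, `[[`, "dir"))
  list(vox = vox, sl = sl, dir = dir)
}

# Sign-align rows of `dirs` within groups `grp` to each group's first row.
sign_align <- function(dirs, grp) {
  first <- !duplicated(grp)
  ref <- dirs[first, , drop = FALSE][grp, , drop = FALSE]
  s <- sign(rowSums(dirs * ref))
  s[s == 0] <- 1
  s
}

#' Remove crossing fibers by per-voxel direction histogram
#'
#' In each voxel, the local travel directions of all traversing streamlines
#' are collected with antipodal symmetry. The modal direction is the
#' observed direction maximizing the fraction of directions within
#' `angle_tol_deg` of itself (a continuous spherical-cap mass; a binned
#' variant with `method = "binned"` discretizes directions into
#' `bin_width_deg` spherical bins first). A streamline is flagged in a voxel
#' when its direction deviates more than `angle_tol_deg` from the mode and
#' fewer than `min_fraction` of the voxel's directions lie within
#' `angle_tol_deg` of its own direction; flagged streamlines are removed in
#' their entirety.
#'
#' @param streamlines a [streamline_set].
#' @param ref [volume3d] (or [orientation_field]) giving grid and affine.
#' @param angle_tol_deg angular tolerance (default +/- 15 degrees).
#' @param min_fraction minimum local direction mass (default 5%).
#' @param method `"cap"` (continuous, default) or `"binned"`.
#' @param bin_width_deg bin width for the binned variant.
#' @return Filtered [streamline_set].
#' @export
filter_crossing <- function(streamlines, ref, angle_tol_deg = 15,
                            min_fraction = 0.05, method = c("cap", "binned"),
                            bin_width_deg = 10) {
  method <- match.arg(method)
  if (inherits(ref, "orientation_field"))
    ref <- volume3d(ref$mask + 0, ref$affine, ref$space)
  if (length(streamlines$points) == 0L) return(streamlines)
  ctol <- cos(angle_tol_deg * pi / 180)
  vd <- voxel_streamline_dirs(streamlines, ref)
  flagged <- rep(FALSE, length(streamlines$points))
  for (v in unique(vd$vox)) {
    sel <- vd$vox == v
    D <- vd$dir[sel, , drop = FALSE]
    sls <- vd$sl[sel]
    k <- nrow(D)
    if (k < 2L) next
    if (method == "binned") D <- bin_directions(D, bin_width_deg)
    C <- abs(D %*% t(D))                    # antipodal angular closeness
    mass <- rowSums(C >= ctol) / k
    mode_i <- which.max(mass)
    off_mode <- C[, mode_i] < ctol
    low_mass <- mass < min_fraction
    flagged[sls[off_mode & low_mass]] <- TRUE
  }
  streamlines[!flagged]
}

# Snap unit directions to the centers of spherical bins of roughly
# `bin_width_deg` angular width (azimuth/inclination grid, antipodal fold).
bin_directions <- function(D, bin_width_deg) {
  w <- bin_width_deg * pi / 180
  # fold to upper hemisphere
  s <- sign(D[, 3]); s[s == 0] <- 1
  D <- D * s
  incl <- acos(pmin(pmax(D[, 3], -1), 1))
  az <- atan2(D[, 2], D[, 1])
  incl_b <- (floor(incl / w) + 0.5) * w
  az_b <- (floor(az / w) + 0.5) * w
  cbind(sin(incl_b) * cos(az_b), sin(incl_b) * sin(az_b), cos(incl_b))
}

#' Declarative bundle query
#'
#' Selects streamlines by their start/end regions, obligatory waypoints and
#' exclusion regions in a parcellation.
#'
#' @param name bundle name.
#' @param start_labels,end_labels nonempty ROI id sets.
#' @param waypoint_labels list of ROI id sets that must each be visited.
#' @param exclusion_labels ROI ids that must not be visited.
#' @return An object of class `bundle_query`.
#' @export
bundle_query <- function(name, start_labels, end_labels,
                         waypoint_labels = list(), exclusion_labels = integer(0)) {
  if (!length(start_labels) || !length(end_labels))
    stop_input("start and end label sets must be nonempty")
  structure(list(name = name, start_labels = as.integer(start_labels),
                 end_labels = as.integer(end_labels),
                 waypoint_labels = lapply(waypoint_labels, as.integer),
                 exclusion_labels = as.integer(exclusion_labels)),
            class = "bundle_query")
}

#' Select streamlines matching a bundle query
#'
#' Keeps streamlines whose first point lies in a start label and last point
#' in an end label (or vice versa; orientation-free), which visit every
#' waypoint set, and which visit no exclusion label.
#'
#' @param streamlines a [streamline_set].
#' @param labels integer-label [volume3d] parcellation.
#' @param query a [bundle_query()].
#' @return The selected [streamline_set].
#' @export
select_by_query <- function(streamlines, labels, query) {
  stopifnot(inherits(query, "bundle_query"))
  present <- unique(labels$grid[labels$grid != 0])
  known <- c(query$start_labels, query$end_labels,
             unlist(query$waypoint_labels), query$exclusion_labels)
  if (length(setdiff(known, present)))
    stop_input("query references label id(s) absent from the parcellation: ",
               paste(setdiff(known, present), collapse = ", "))
  dims <- dim(labels$grid)
  keep <- vapply(streamlines$points, function(p) {
    ends <- world_to_index(labels, p[c(1, nrow(p)), , drop = FALSE])
    lin <- voxel_linear(ends, dims)
    lend <- c(0L, 0L)
    for (j in 1:2) if (!is.na(lin[j])) lend[j] <- labels$grid[lin[j]]
    endpoint_ok <- (lend[1] %in% query$start_labels && lend[2] %in% query$end_labels) ||
      (lend[1] %in% query$end_labels && lend[2] %in% query$start_labels)
    if (!endpoint_ok) return(FALSE)
    visited <- unique(labels$grid[streamline_voxels(p, labels$affine, dims)])
    if (length(intersect(visited, query$exclusion_labels))) return(FALSE)
    all(vapply(query$waypoint_labels, function(w) length(intersect(visited, w)) > 0, TRUE))
  }, TRUE)
  streamlines[keep]
}

#' Build a probabilistic bundle atlas from control subjects
#'
#' Per voxel, the fraction of contributing subjects with at least one
#' streamline of the bundle intersecting it.
#'
#' @param subject_sets named list mapping subject id to that subject's
#'   [streamline_set] for one bundle.
#' @param ref [volume3d] template grid.
#' @return [volume3d] of membership probabilities with attribute
#'   `n_subjects`.
#' @export
build_bundle_atlas <- function(subject_sets, ref) {
  if (!length(subject_sets)) stop_input("empty subject map")
  dims <- dim(ref$grid)
  counts <- numeric(prod(dims))
  for (sls in subject_sets) {
    vis <- unique(unlist(set_voxels(sls, ref), use.names = FALSE))
    counts[vis] <- counts[vis] + 1
  }
  out <- volume3d(array(counts / length(subject_sets), dims), ref$affine, ref$space)
  attr(out, "n_subjects") <- length(subject_sets)
  out
}

#' Project a statistical blob onto atlas bundles
#'
#' For each bundle, the fraction of blob voxels whose atlas membership
#' probability is at least `min_bundle_prob` (default 25%); a voxel may
#' belong to several bundles. Bundles with positive fraction are reported,
#' ranked by fraction.
#'
#' @param blob binary [volume3d] of the cluster-corrected result.
#' @param atlas named list of per-bundle probability volumes
#'   ([build_bundle_atlas()] outputs).
#' @param min_bundle_prob per-voxel probability threshold.
#' @return Data frame `bundle`, `fraction`, `n_blob_voxels`, ranked.
#' @export
project_blob_to_bundles <- function(blob, atlas, min_bundle_prob = 0.25) {
  vox <- which(blob$grid > 0)
  if (!length(vox)) stop_input("empty blob")
  rows <- lapply(names(atlas), function(b) {
    check_same_space(blob, atlas[[b]], "blob and atlas")
    frac <- mean(atlas[[b]]$grid[vox] >= min_bundle_prob)
    data.frame(bundle = b, fraction = frac, n_blob_voxels = length(vox))
  })
  out <- do.call(rbind, rows)
  out <- out[out$fraction > 0, , drop = FALSE]
  out[order(-out$fraction), , drop = FALSE]
}
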