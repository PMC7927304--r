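#' Tubular fiber-bundle geometry
#'
#' A bundle is a tube of constant radius around a polyline centerline, with
#' gray-matter-like label regions at its two ends (and optionally at
#' waypoints along the curve).
#'
#' @param name bundle name.
#' @param centerline n x 3 matrix of world-mm control points (straight
#'   segments are interpolated between them).
#' @param radius_mm tube radius.
#' @param start_label,end_label integer ROI ids placed at the curve ends.
#' @param waypoint_labels optional list of `list(label=, at=, len=)`, placing
#'   a label over voxels whose centerline arc-length falls within `len`/2 of
#'   fraction `at` of the total length.
#' @return An object of class `bundle_geometry`.
#' @export
bundle_geometry <- function(name, centerline, radius_mm,
                            start_label, end_label, waypoint_labels = NULL) {
  centerline <- rbind_pts(centerline)
  if (nrow(centerline) < 2L) stop_input("centerline needs at least 2 points")
  check_number(radius_mm, "radius_mm", 0, Inf, closed_lower = FALSE)
  structure(list(name = name, centerline = centerline, radius_mm = radius_mm,
                 start_label = as.integer(start_label),
                 end_label = as.integer(end_label),
                 waypoint_labels = waypoint_labels),
            class = "bundle_geometry")
}

#' Specification of a synthetic diffusion phantom
#'
#' Defines the template grid, the fiber bundles, the location of the true
#' group-effect region ("blob") and of the true accuracy-correlate region,
#' the effect sizes embedded in subject FA maps, and the noise level. The
#' default phantom is two orthogonal straight bundles crossing at the grid
#' center, with the group effect on the x-aligned bundle and the
#' interoceptive-accuracy correlate on the y-aligned bundle.
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param voxel_size mm per axis.
#' @param bundles list of [bundle_geometry()] objects; `NULL` for the default
#'   two-bundle crossing phantom.
#' @param blob_region,correlate_region `list(bundle=, lo=, hi=)`: tube voxels
#'   of the named bundle whose centers fall in the world box `[lo, hi]`.
#' @param group_effect FA offset added in the blob for patients (unitless FA).
#' @param slope FA change per unit of (true accuracy - `accuracy_ref`) in the
#'   correlate region.
#' @param accuracy_ref accuracy centering constant for the correlate effect.
#' @param fa_baseline FA inside bundle tubes; `fa_background` elsewhere.
#' @param noise_sd additive Gaussian FA noise SD (> 0).
#' @param age_slope,sex_effect small nuisance covariate effects applied over
#'   the whole white-matter mask.
#' @param roi_len_mm length of the end-label regions along the centerline.
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(36, 36, 12), voxel_size = c(1, 1, 1),
                         bundles = NULL,
                         blob_region = list(bundle = "bundle_x", lo = c(7.5, 0, 0),
                                            hi = c(13.5, 36, 12)),
                         correlate_region = list(bundle = "bundle_y", lo = c(0, 19.5, 0),
                                                 hi = c(36, 25.5, 12)),
                         group_effect = -0.15, slope = 0.5, accuracy_ref = 0.65,
                         fa_baseline = 0.5, fa_background = 0.1,
                         noise_sd = 0.08, age_slope = -5e-4, sex_effect = 0.01,
                         roi_len_mm = 3, seed = 1L) {
  grid_shape <- vapply(grid_shape, check_count, 0L, name = "grid_shape", min = 4L)
  voxel_size <- rep_len(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop_input("voxel sizes must be positive")
  check_number(noise_sd, "noise_sd", 0, Inf)
  if (is.null(bundles)) {
    ext <- grid_shape * voxel_size
    mid <- ext / 2
    bundles <- list(
      bundle_geometry("bundle_x",
                      rbind(c(2.5, mid[2] - 6, mid[3]), c(ext[1] - 2.5, mid[2] - 6, mid[3])),
                      radius_mm = 2.2, start_label = 1L, end_label = 2L),
      bundle_geometry("bundle_y",
                      rbind(c(mid[1], 2.5, mid[3]), c(mid[1], ext[2] - 2.5, mid[3])),
                      radius_mm = 2.2, start_label = 3L, end_label = 4L))
  }
  if (!length(bundles) || !all(vapply(bundles, inherits, TRUE, "bundle_geometry")))
    stop_input("'bundles' must be a list of bundle_geometry objects")
  names(bundles) <- vapply(bundles, `[[`, "", "name")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 bundles = bundles, blob_region = blob_region,
                 correlate_region = correlate_region,
                 group_effect = group_effect, slope = slope,
                 accuracy_ref = accuracy_ref, fa_baseline = fa_baseline,
                 fa_background = fa_background, noise_sd = noise_sd,
                 age_slope = age_slope, sex_effect = sex_effect,
                 roi_len_mm = roi_len_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Distance from points P (n x 3) to a polyline; returns the distance, the
# unit tangent of the nearest segment, and the arc-length of the projection.
polyline_distance <- function(P, line) {
  n <- nrow(P)
  best <- rep(Inf, n)
  tangent <- matrix(0, n, 3)
  arc <- numeric(n)
  s0 <- 0
  for (k in seq_len(nrow(line) - 1L)) {
    a <- line[k, ]; b <- line[k + 1L, ]
    ab <- b - a; L2 <- sum(ab^2); L <- sqrt(L2)
    t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] + (P[, 3] - a[3]) * ab[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- P[, 1] - (a[1] + t * ab[1])
    dy <- P[, 2] - (a[2] + t * ab[2])
    dz <- P[, 3] - (a[3] + t * ab[3])
    d <- sqrt(dx^2 + dy^2 + dz^2)
    upd <- d < best
    if (any(upd)) {
      best[upd] <- d[upd]
      tangent[upd, ] <- matrix(ab / L, sum(upd), 3, byrow = TRUE)
      arc[upd] <- s0 + t[upd] * L
    }
    s0 <- s0 + L
  }
  list(dist = best, tangent = tangent, arc = arc, total_length = s0)
}

#' Orientation field of a phantom
#'
#' Per-voxel primary (and, in crossing regions, secondary) unit fiber
#' orientations with antipodal equivalence (v and -v are the same
#' orientation); voxels outside all tubes carry a null orientation.
#'
#' @param primary,secondary X x Y x Z x 3 arrays (secondary may be NULL).
#' @param mask logical white-matter array.
#' @param affine voxel-to-world matrix.
#' @param space space tag.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(primary, secondary = NULL, mask, affine,
                              space = "phantom") {
  structure(list(primary = primary, secondary = secondary, mask = mask,
                 affine = affine, space = space),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$primary)[1:3]
  cat(sprintf("<orientation_field> %d x %d x %d voxels, %d in mask, %s\n",
              d[1], d[2], d[3], sum(x$mask),
              if (is.null(x$secondary)) "single population" else "with crossing population"))
  invisible(x)
}

#' Generate a phantom: orientation field, masks, labels, ground truth
#'
#' Each bundle contributes a tube of voxels whose orientation follows its
#' centerline tangent. Where tubes overlap, the nearest bundle supplies the
#' primary orientation and the other the recorded secondary (crossing)
#' orientation. End and waypoint labels are placed on the tube at the stated
#' curve locations; overlapping labels from different regions are an error.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `phantom` with elements `field`
#'   ([orientation_field]), `wm_mask` ([volume3d], binary), `labels`
#'   ([volume3d], integer), `truth` (ground-truth voxel sets and bundle
#'   membership) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  affine <- make_affine(spec$voxel_size, origin = spec$voxel_size / 2)
  nvox <- prod(dims)
  idx0 <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                z = 0:(dims[3] - 1)))
  centers <- voxel_to_world(affine, idx0)
  nb <- length(spec$bundles)
  dist <- matrix(Inf, nvox, nb)
  arcs <- matrix(NA_real_, nvox, nb)
  tangents <- vector("list", nb)
  lengths <- numeric(nb)
  for (j in seq_len(nb)) {
    b <- spec$bundles[[j]]
    pd <- polyline_distance(centers, b$centerline)
    dist[, j] <- pd$dist
    arcs[, j] <- pd$arc
    tangents[[j]] <- pd$tangent
    lengths[j] <- pd$total_length
    ext <- dims * spec$voxel_size
    if (any(b$centerline < b$radius_mm - 1e-9) ||
        any(sweep(b$centerline, 2L, ext, `-`) > -(b$radius_mm - 1e-9)))
      stop_input("bundle '", b$name, "' tube extends outside the grid")
  }
  inside <- sweep(dist, 2L, vapply(spec$bundles, `[[`, 0, "radius_mm"), `<=`)
  wm <- rowSums(inside) > 0
  primary <- array(0, c(dims, 3L))
  secondary <- array(0, c(dims, 3L))
  has_secondary <- FALSE
  lin <- seq_len(nvox)
  dmask <- ifelse(inside, dist, Inf)
  if (nb == 1L) {
    ord <- rbind(rep(1L, nvox), rep(NA_integer_, nvox))
  } else {
    ord <- apply(dmask, 1L, function(r) order(r)[1:2])
  }
  for (j in seq_len(nb)) {
    pri <- wm & ord[1, ] == j & inside[cbind(lin, j)]
    for (ax in 1:3) primary[cbind(idx0[pri, , drop = FALSE] + 1L, ax)] <-
        tangents[[j]][pri, ax]
    if (nb > 1L) {
      sec <- wm & ord[2, ] == j & inside[cbind(lin, j)]
      if (any(sec)) {
        has_secondary <- TRUE
        for (ax in 1:3) secondary[cbind(idx0[sec, , drop = FALSE] + 1L, ax)] <-
            tangents[[j]][sec, ax]
      }
    }
  }
  wm_arr <- array(wm, dims)
  # labels: tube ends (by projected arc-length) and declared waypoints
  labels <- array(0L, dims)
  place_label <- function(labels, sel, label, what) {
    clash <- sel & labels != 0L & labels != label
    if (any(clash))
      stop_input("overlapping ROI labels at ", sum(clash), " voxels (", what, ")")
    labels[sel] <- label
    labels
  }
  for (j in seq_len(nb)) {
    b <- spec$bundles[[j]]
    in_tube <- inside[, j]
    sel_start <- array(in_tube & arcs[, j] <= spec$roi_len_mm, dims)
    sel_end <- array(in_tube & arcs[, j] >= lengths[j] - spec$roi_len_mm, dims)
    labels <- place_label(labels, sel_start, b$start_label, paste0(b$name, " start"))
    labels <- place_label(labels, sel_end, b$end_label, paste0(b$name, " end"))
    for (wp in b$waypoint_labels %||% list()) {
      s <- wp$at * lengths[j]
      sel <- array(in_tube & abs(arcs[, j] - s) <= wp$len / 2, dims)
      labels <- place_label(labels, sel, as.integer(wp$label), paste0(b$name, " waypoint"))
    }
  }
  region_voxels <- function(region) {
    j <- match(region$bundle, names(spec$bundles))
    if (is.na(j)) stop_input("unknown bundle '", region$bundle, "' in region spec")
    sel <- inside[, j] &
      centers[, 1] >= region$lo[1] & centers[, 1] <= region$hi[1] &
      centers[, 2] >= region$lo[2] & centers[, 2] <= region$hi[2] &
      centers[, 3] >= region$lo[3] & centers[, 3] <= region$hi[3]
    which(sel)
  }
  blob <- region_voxels(spec$blob_region)
  correlate <- region_voxels(spec$correlate_region)
  if (!length(blob)) stop_input("blob region is empty")
  if (!all(wm[blob])) stop_input("blob region falls outside the white-matter mask")
  truth <- list(
    blob = blob, correlate = correlate,
    blob_bundle = spec$blob_region$bundle,
    correlate_bundle = spec$correlate_region$bundle,
    bundles = stats::setNames(lapply(seq_len(nb), function(j) {
      b <- spec$bundles[[j]]
      list(start_label = b$start_label, end_label = b$end_label,
           voxels = which(inside[, j]))
    }), names(spec$bundles)))
  structure(list(
    field = orientation_field(primary,
                              if (has_secondary) secondary else NULL,
                              wm_arr, affine),
    wm_mask = volume3d(wm_arr + 0, affine),
    labels = volume3d(labels, affine),
    truth = truth, spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s grid, %d bundles, %d white-matter voxels\n",
              paste(x$spec$grid_shape, collapse = " x "),
              length(x$spec$bundles), sum(x$field$mask)))
  cat(sprintf("  blob: %d voxels on %s; correlate: %d voxels on %s\n",
              length(x$truth$blob), x$truth$blob_bundle,
              length(x$truth$correlate), x$truth$correlate_bundle))
  invisible(x)
}

#' Generate per-subject FA volumes with embedded effects
#'
#' FA is the tube baseline plus, for patients, the group effect inside the
#' true blob; plus the accuracy slope inside the correlate region; plus
#' small age/sex nuisance effects over the mask; plus Gaussian noise;
#' clipped to \[0, 1\]. A warning is logged when clipping affects more than
#' half the drawn values.
#'
#' @param phantom a [generate_phantom()] result.
#' @param cohort a [generate_cohort()] table.
#' @param noise_sd overrides the spec's noise SD if given.
#' @param seed integer seed (default: the phantom spec's).
#' @return Object of class `fa_stack`: list with `data` (X x Y x Z x n
#'   array), `affine`, `ids`, `space`.
#' @export
generate_subject_fa <- function(phantom, cohort, noise_sd = NULL, seed = NULL) {
  spec <- phantom$spec
  sdn <- noise_sd %||% spec$noise_sd
  seed <- seed %||% spec$seed
  dims <- spec$grid_shape
  nvox <- prod(dims)
  n <- nrow(cohort)
  wm <- as.vector(phantom$field$mask)
  base <- ifelse(wm, spec$fa_baseline, spec$fa_background)
  patient <- cohort$group != "HC"
  agec <- cohort$age - mean(cohort$age)
  sexm <- as.numeric(cohort$sex == "M")
  acc <- cohort$true_accuracy - spec$accuracy_ref
  with_seed(seed, {
    data <- array(0, c(dims, n))
    n_clipped <- 0
    for (i in seq_len(n)) {
      mu <- base
      if (patient[i]) mu[phantom$truth$blob] <- mu[phantom$truth$blob] + spec$group_effect
      mu[phantom$truth$correlate] <- mu[phantom$truth$correlate] + spec$slope * acc[i]
      mu[wm] <- mu[wm] + spec$age_slope * agec[i] + spec$sex_effect * sexm[i]
      v <- mu + if (sdn > 0) stats::rnorm(nvox, 0, sdn) else 0
      n_clipped <- n_clipped + sum(v < 0 | v > 1)
      data[, , , i] <- pmin(pmax(v, 0), 1)
    }
    if (n_clipped > 0.5 * nvox * n)
      warning("FA clipping affected more than half of all drawn values",
              call. = FALSE)
    structure(list(data = data, affine = phantom$field$affine,
                   ids = cohort$id, space = "phantom"),
              class = "fa_stack")
  })
}

#' @export
print.fa_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fa_stack> %d subjects on a %d x %d x %d grid\n", d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Extract one subject's volume from an FA stack
#'
#' @param stack an `fa_stack`.
#' @param i subject index or id.
#' @return A [volume3d].
#' @export
stack_volume <- function(stack, i) {
  if (is.character(i)) i <- match(i, stack$ids)
  volume3d(stack$data[, , , i], stack$affine, stack$space)
}

#' Seed points along a bundle's tube for tracking
#'
#' Seeds are placed at regular arc-length steps along the centerline with
#' uniform radial jitter inside the tube.
#'
#' @param phantom a phantom.
#' @param bundle bundle name.
#' @param n number of seeds.
#' @param jitter_frac radial jitter as a fraction of the tube radius.
#' @param seed integer seed.
#' @return n x 3 matrix of world-mm seed points.
#' @export
bundle_seeds <- function(phantom, bundle, n = 100, jitter_frac = 0.5, seed = 1L) {
  b <- phantom$spec$bundles[[bundle]]
  if (is.null(b)) stop_input("unknown bundle '", bundle, "'")
  line <- b$centerline
  segs <- diff(line)
  seglen <- sqrt(rowSums(segs^2))
  total <- sum(seglen)
  with_seed(seed, {
    s <- seq(0.05, 0.95, length.out = n) * total
    cum <- c(0, cumsum(seglen))
    k <- findInterval(s, cum, rightmost.closed = TRUE)
    t <- (s - cum[k]) / seglen[k]
    pts <- line[k, , drop = FALSE] + segs[k, , drop = FALSE] * t
    jit <- matrix(stats::rnorm(3 * n), n, 3)
    jit <- jit - (rowSums(jit * segs[k, , drop = FALSE]) / seglen[k]^2) * segs[k, , drop = FALSE]
    nrm <- sqrt(rowSums(jit^2)); nrm[nrm == 0] <- 1
    r <- b$radius_mm * jitter_frac * stats::runif(n)^(1 / 2)
    pts + jit / nrm * r
  })
}
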