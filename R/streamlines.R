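#' Set of streamlines in world coordinates
#'
#' Streamlines are ordered 3-D polylines in world millimetres. Each has at
#' least two points; consecutive points must be distinct.
#'
#' @param points list of n x 3 numeric matrices (world mm).
#' @param subject subject identifier(s), recycled across streamlines.
#' @param seed_label optional originating ROI id per streamline.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(points, subject = NA_character_, seed_label = NA_integer_) {
  if (!is.list(points)) stop_input("'points' must be a list of matrices")
  points <- lapply(points, function(p) {
    p <- rbind_pts(p)
    if (nrow(p) < 2L) stop_input("each streamline needs at least 2 points")
    if (any(!is.finite(p))) stop_input("streamline coordinates must be finite")
    if (any(rowSums(abs(diff(p))) == 0))
      stop_input("consecutive streamline points must be distinct")
    p
  })
  n <- length(points)
  structure(list(points = points,
                 subject = rep_len(as.character(subject), max(n, 0L)),
                 seed_label = rep_len(as.integer(seed_label), max(n, 0L))),
            class = "streamline_set")
}

#' Number of streamlines in a set
#' @param x a `streamline_set`.
#' @export
n_streamlines <- function(x) length(x$points)

#' @export
length.streamline_set <- function(x) length(x$points)

#' @export
`[.streamline_set` <- function(x, i) {
  structure(list(points = x$points[i],
                 subject = x$subject[i],
                 seed_label = x$seed_label[i]),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$points, nrow, 0L)
  cat(sprintf("<streamline_set> %d streamlines, %d points total (%s per line)\n",
              length(x$points), sum(np),
              if (length(np)) sprintf("%d-%d", min(np), max(np)) else "0"))
  invisible(x)
}

#' Concatenate streamline sets
#' @param ... `streamline_set` objects.
#' @export
c.streamline_set <- function(...) {
  sets <- list(...)
  structure(list(points = do.call(c, lapply(sets, `[[`, "points")),
                 subject = do.call(c, lapply(sets, `[[`, "subject")),
                 seed_label = do.call(c, lapply(sets, `[[`, "seed_label"))),
            class = "streamline_set")
}

# ---- voxel traversal -------------------------------------------------------

# Enumerate all voxels a polyline passes through, on the half-open 0-based
# grid (voxel i spans [i-0.5, i+0.5) in continuous voxel coordinates).
# Returns, per traversed (voxel, segment) pair, the linear voxel id and the
# segment index; exact plane-crossing enumeration, fully vectorized over
# segments.
traverse_polyline <- function(points, affine, dims) {
  v <- world_to_voxel(affine, points)      # continuous voxel coords
  n <- nrow(v)
  nseg <- n - 1L
  d <- v[-1, , drop = FALSE] - v[-n, , drop = FALSE]
  segs_all <- rep.int(seq_len(nseg), 2L)
  ts_all <- c(rep.int(0, nseg), rep.int(1, nseg))
  for (ax in 1:3) {
    a0 <- v[-n, ax]; a1 <- v[-1, ax]
    lo <- pmin(a0, a1); hi <- pmax(a0, a1)
    k0 <- ceiling(lo + 0.5); k1 <- floor(hi + 0.5)
    cnt <- pmax(0L, as.integer(k1 - k0 + 1))
    cnt[d[, ax] == 0] <- 0L
    if (sum(cnt) == 0L) next
    sid <- rep.int(seq_len(nseg), cnt)
    ks <- sequence(cnt) - 1 + k0[sid] - 0.5
    segs_all <- c(segs_all, sid)
    ts_all <- c(ts_all, (ks - a0[sid]) / d[sid, ax])
  }
  ts_all <- pmin(pmax(ts_all, 0), 1)
  o <- order(segs_all, ts_all)
  s_o <- segs_all[o]; t_o <- ts_all[o]
  m <- length(o)
  same <- s_o[-1] == s_o[-m]
  dt <- t_o[-1] - t_o[-m]
  keep <- same & dt > 1e-12
  mid_t <- (t_o[-1] + t_o[-m])[keep] / 2
  mid_s <- s_o[-1][keep]
  P <- v[mid_s, , drop = FALSE] + d[mid_s, , drop = FALSE] * mid_t
  idx <- floor(P + 0.5)
  # the polyline's own endpoints count even when they sit exactly on a
  # voxel boundary (half-open: the boundary point belongs to the upper voxel)
  idx <- rbind(idx, floor(v[c(1L, n), , drop = FALSE] + 0.5))
  mid_s <- c(mid_s, 1L, nseg)
  vox <- voxel_linear(idx, dims)
  ok <- !is.na(vox)
  # unit world-space segment directions
  w <- voxel_to_world(affine, v)
  dw <- w[-1, , drop = FALSE] - w[-n, , drop = FALSE]
  dw <- dw / sqrt(rowSums(dw^2))
  list(vox = vox[ok], seg = mid_s[ok], dir = dw)
}

# Unique linear voxel ids visited by one streamline.
streamline_voxels <- function(points, affine, dims) {
  unique(traverse_polyline(points, affine, dims)$vox)
}

# For a whole set: list of unique-voxel vectors, one per streamline.
set_voxels <- function(streamlines, ref) {
  dims <- dim(ref$grid)
  lapply(streamlines$points, streamline_voxels, affine = ref$affine, dims = dims)
}
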