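#' Scalar 3-D volume with a world affine
#'
#' A minimal container for scalar, binary (mask) and integer-labeled 3-D grids.
#' The affine maps 0-based voxel indices (voxel centers) to world RAS+
#' coordinates in millimetres; voxel boxes are half-open around the center.
#'
#' @param grid numeric 3-D array.
#' @param affine invertible 4x4 voxel-to-world matrix (mm). Defaults to an
#'   axis-aligned 1 mm grid anchored at the origin.
#' @param space character tag naming the template space; volumes entering a
#'   joint analysis must share it.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(grid, affine = NULL, space = "phantom") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop_input("'grid' must be a 3-D array")
  if (any(!is.finite(grid) & !is.na(grid)))
    stop_input("'grid' contains non-finite values")
  if (is.null(affine)) affine <- make_affine(c(1, 1, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop_input("'affine' must be an invertible 4x4 matrix")
  structure(list(grid = grid, affine = affine, space = space),
            class = "volume3d")
}

#' Axis-aligned voxel-to-world affine
#'
#' @param voxel_size mm per axis (length 3, recycled).
#' @param origin world coordinate of voxel (0,0,0), mm.
#' @return 4x4 matrix.
#' @export
make_affine <- function(voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_size <- rep_len(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop_input("voxel sizes must be positive")
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- origin
  a
}

#' @export
dim.volume3d <- function(x) dim(x$grid)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$grid)
  vs <- voxel_sizes(x)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space '%s'\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], x$space))
  rng <- range(x$grid, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

voxel_sizes <- function(vol) {
  a <- if (inherits(vol, "volume3d")) vol$affine else vol
  sqrt(colSums(a[1:3, 1:3]^2))
}

#' Convert world coordinates to continuous 0-based voxel coordinates
#'
#' @param vol a `volume3d` (or 4x4 affine).
#' @param pts n x 3 matrix of world mm points.
#' @return n x 3 matrix of continuous voxel coordinates (voxel centers at
#'   integers, 0-based).
#' @export
world_to_voxel <- function(vol, pts) {
  a <- if (inherits(vol, "volume3d")) vol$affine else vol
  pts <- rbind_pts(pts)
  v <- solve(a, rbind(t(pts), 1))
  t(v[1:3, , drop = FALSE])
}

#' Convert 0-based voxel coordinates to world coordinates
#'
#' @inheritParams world_to_voxel
#' @param idx n x 3 matrix of (possibly fractional) 0-based voxel coordinates.
#' @return n x 3 matrix of world mm points.
#' @export
voxel_to_world <- function(vol, idx) {
  a <- if (inherits(vol, "volume3d")) vol$affine else vol
  idx <- rbind_pts(idx)
  w <- a %*% rbind(t(idx), 1)
  t(w[1:3, , drop = FALSE])
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  storage.mode(pts) <- "double"
  pts
}

# 0-based integer voxel index of world points (half-open boxes around centers).
world_to_index <- function(vol, pts) {
  v <- world_to_voxel(vol, pts)
  floor(v + 0.5)
}

# Linear (1-based) index from a matrix of 0-based voxel triplets; NA outside.
voxel_linear <- function(idx, dims) {
  inside <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
    idx[, 2] >= 0 & idx[, 2] < dims[2] &
    idx[, 3] >= 0 & idx[, 3] < dims[3]
  out <- rep(NA_integer_, nrow(idx))
  out[inside] <- 1L + idx[inside, 1] + dims[1] * (idx[inside, 2] + dims[2] * idx[inside, 3])
  out
}

check_same_space <- function(a, b, what = "volumes") {
  if (!identical(dim(a$grid), dim(b$grid)) ||
      max(abs(a$affine - b$affine)) > 1e-6 ||
      !identical(a$space, b$space))
    stop_input(sprintf("%s are not aligned (grid/affine/space mismatch)", what))
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param space space tag to attach.
#' @return A [volume3d].
#' @export
read_volume <- function(path, space = "phantom") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_input("malformed NIfTI file '", path,
                                                 "': ", conditionMessage(e)))
  g <- as.array(img)
  if (length(dim(g)) != 3L) stop_input("expected a 3-D NIfTI volume in '", path, "'")
  volume3d(g, affine = structure(RNifti::xform(img), code = NULL, dimnames = NULL),
           space = space)
}

#' Write a volume as NIfTI
#'
#' @param vol a [volume3d].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- voxel_sizes(vol)
  sf <- structure(vol$affine, code = 2L)
  img <- RNifti::`sform<-`(img, sf)
  img <- RNifti::`qform<-`(img, sf)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Display one axial slice of a volume
#'
#' @param x a [volume3d].
#' @param z 0-based slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.volume3d <- function(x, z = NULL, ...) {
  d <- dim(x$grid)
  z <- if (is.null(z)) (d[3] - 1L) %/% 2L else check_count(z, "z")
  graphics::image(seq_len(d[1]), seq_len(d[2]), x$grid[, , z + 1L],
                  xlab = "x (voxel)", ylab = "y (voxel)",
                  col = grDevices::gray.colors(64), useRaster = TRUE, ...)
  invisible(x)
}
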