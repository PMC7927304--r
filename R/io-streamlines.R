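#' Read and write streamlines in TCK (MRtrix) format
#'
#' TCK stores world-mm coordinates as little-endian float32 triplets,
#' streamlines separated by NaN triplets and terminated by an Inf triplet.
#'
#' @param streamlines a [streamline_set].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- "mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n"
  # two-pass offset: header length depends on its own printed size
  n <- length(streamlines$points)
  off <- nchar(sprintf(header, n, 0))
  repeat {
    off2 <- nchar(sprintf(header, n, off))
    if (off2 == off) break
    off <- off2
  }
  writeChar(sprintf(header, n, off), con, eos = NULL)
  for (p in streamlines$points) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(raw) < 16L || !identical(rawToChar(raw[1:13]), "mrtrix tracks") ||
      length(hdr_end) == 0L)
    stop_input("malformed TCK file '", path, "': missing 'mrtrix tracks' magic")
  txt <- rawToChar(raw[seq_len(hdr_end + 3L)])
  m <- regexpr("file: \\. (\\d+)", txt)
  if (m < 0) stop_input("malformed TCK file '", path, "': missing 'file' field")
  off <- as.integer(sub(".*file: \\. (\\d+).*", "\\1", substr(txt, m, m + attr(m, "match.length"))))
  dt <- regmatches(txt, regexpr("datatype: [A-Za-z0-9]+", txt))
  if (length(dt) && !grepl("Float32LE", dt))
    stop_input("unsupported TCK datatype in '", path, "': ", dt)
  vals <- readBin(raw[(off + 1L):length(raw)], "numeric", size = 4L,
                  n = (length(raw) - off) %/% 4L, endian = "little")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  breaks <- which(is.nan(pts[, 1]) | is.infinite(pts[, 1]))
  out <- list(); start <- 1L
  for (b in breaks) {
    if (b > start) out[[length(out) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is.infinite(pts[b, 1])) break
  }
  streamline_set(out)
}

#' Read and write streamlines in TRK (TrackVis v2) format
#'
#' TRK stores points in corner-based "voxel-mm" coordinates; the 4x4
#' voxel-to-world matrix in the header is used to convert to and from the
#' world-mm convention used throughout this package.
#'
#' @param streamlines a [streamline_set].
#' @param path file path.
#' @param ref a [volume3d] supplying grid dimensions and affine.
#' @return `path` invisibly for the writer; a [streamline_set] for the reader.
#' @export
write_trk <- function(streamlines, path, ref) {
  dims <- dim(ref$grid); vs <- voxel_sizes(ref)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL); writeBin(raw(1), con)
  writeBin(as.integer(dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")  # origin
  writeBin(0L, con, size = 2L, endian = "little")                      # n_scalars
  writeBin(raw(200), con)                                             # scalar names
  writeBin(0L, con, size = 2L, endian = "little")                      # n_properties
  writeBin(raw(200), con)                                             # property names
  writeBin(as.numeric(ref$affine), con, size = 4L, endian = "little")  # vox_to_ras
  writeBin(raw(444), con)                                             # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1), con) # voxel_order
  writeBin(raw(4), con)                                               # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  writeBin(raw(2), con)                                               # pad1
  writeBin(raw(6), con)                                               # invert/swap flags
  writeBin(length(streamlines$points), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")                      # version
  writeBin(1000L, con, size = 4L, endian = "little")                   # hdr_size
  for (p in streamlines$points) {
    v <- world_to_voxel(ref, p)                 # center-based voxel coords
    vm <- sweep(v + 0.5, 2L, vs, `*`)           # corner-based voxel-mm
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(vm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 1000L || rawToChar(raw[1:5]) != "TRACK")
    stop_input("malformed TRK file '", path, "': missing TRACK magic")
  rd <- function(from, what, n, size) readBin(raw[(from + 1L):length(raw)], what,
                                              n = n, size = size, endian = "little")
  vs <- rd(12L, "numeric", 3L, 4L)
  affine <- matrix(rd(440L, "numeric", 16L, 4L), 4L, 4L)
  n_scalars <- rd(36L, "integer", 1L, 2L)
  n_props <- rd(238L, "integer", 1L, 2L)
  if (n_scalars != 0L || n_props != 0L)
    stop_input("TRK file '", path, "' with scalars/properties is not supported")
  hdr_size <- rd(996L, "integer", 1L, 4L)
  if (hdr_size != 1000L) stop_input("malformed TRK file '", path, "': hdr_size != 1000")
  if (abs(det(affine)) < 1e-12)
    stop_input("TRK file '", path, "' lacks a valid vox_to_ras matrix")
  pos <- 1000L
  out <- list()
  while (pos + 4L <= length(raw)) {
    np <- rd(pos, "integer", 1L, 4L); pos <- pos + 4L
    vals <- rd(pos, "numeric", 3L * np, 4L); pos <- pos + 12L * np
    vm <- matrix(vals, ncol = 3L, byrow = TRUE)
    v <- sweep(vm, 2L, vs, `/`) - 0.5
    out[[length(out) + 1L]] <- voxel_to_world(affine, v)
  }
  streamline_set(out)
}
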