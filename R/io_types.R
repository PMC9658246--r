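#' @useDynLib octseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Core data types and coordinate conventions.
#
# Axial convention used throughout the package: z = 0 is the TOP edge of the
# scan volume (shallowest depth, nearest the scan head); z grows with depth.
# The fingertip is aligned towards the top edge, so "closest to the topside"
# always means SMALLEST z. Surface heights are continuous (fractional voxel
# units, 0-based); holes are represented by NA, never by an in-band number.
# ---------------------------------------------------------------------------

#' OCT volume
#'
#' A volumetric OCT scan: a 3D intensity grid indexed `[x, y, z]` with voxel
#' pitch metadata. `z = 0` (array index 1) is the top edge of the scan,
#' nearest the scan head; z increases with depth. One column of constant
#' (x, y) is an A-scan.
#'
#' @param data Numeric 3D array, dimensions `(Nx, Ny, Nz)`, all finite.
#' @param pitch Numeric length-3 vector: lateral x, lateral y and axial voxel
#'   pitch in micrometres.
#' @param dtype `"uint8"` (values in `[0, 255]`, integral) or `"float32"`
#'   (any finite values; the scanner-native format).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, pitch = c(20, 20, 5.5), dtype = "float32") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!dtype %in% c("uint8", "float32"))
    stop("`dtype` must be \"uint8\" or \"float32\"", call. = FALSE)
  if (any(dim(data) < 1L)) stop("empty volume", call. = FALSE)
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("`pitch` must be 3 positive voxel pitches in micrometres",
         call. = FALSE)
  structure(list(data = data, pitch = pitch, dtype = dtype),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %d x %d x %d voxels, %s, pitch %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$dtype, x$pitch[1], x$pitch[2], x$pitch[3]))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' Surface heightmap
#'
#' A 2D grid assigning each lateral position one axial height in fractional
#' voxel units (0-based, `0 <= h <= Nz - 1`). Holes (positions where no
#' surface was found) are `NA`.
#'
#' @param heights Numeric matrix `(Nx, Ny)`; `NA` marks a hole.
#' @param nz Axial extent of the source volume (heights must stay within
#'   `[0, nz - 1]`).
#' @param pitch Voxel pitch of the source volume (micrometres), for metadata.
#' @return An object of class `oct_surface`.
#' @export
oct_surface <- function(heights, nz, pitch = c(20, 20, 5.5)) {
  if (!is.matrix(heights)) stop("`heights` must be a matrix", call. = FALSE)
  hv <- heights[!is.na(heights)]
  if (length(hv) && (min(hv) < 0 || max(hv) > nz - 1))
    stop("surface heights outside [0, Nz - 1]", call. = FALSE)
  structure(list(heights = heights, nz = as.integer(nz),
                 pitch = as.numeric(pitch)),
            class = "oct_surface")
}

#' @export
print.oct_surface <- function(x, ...) {
  d <- dim(x$heights)
  nh <- sum(is.na(x$heights))
  cat(sprintf("<oct_surface> %d x %d, %d hole%s, z range [%.2f, %.2f] of [0, %d]\n",
              d[1], d[2], nh, if (nh == 1) "" else "s",
              suppressWarnings(min(x$heights, na.rm = TRUE)),
              suppressWarnings(max(x$heights, na.rm = TRUE)), x$nz - 1L))
  invisible(x)
}

#' @export
dim.oct_surface <- function(x) dim(x$heights)

#' Fingertip coverage mask
#'
#' 2D boolean lateral map; `TRUE` = lateral position covered by the
#' fingertip. After finalization ([refine_mask()]) the `TRUE` set is a single
#' 4-connected component without interior holes.
#'
#' @param bits Logical matrix `(Nx, Ny)`.
#' @return An object of class `oct_mask`.
#' @export
oct_mask <- function(bits) {
  if (!is.matrix(bits) || !is.logical(bits))
    stop("`bits` must be a logical matrix", call. = FALSE)
  bits[is.na(bits)] <- FALSE
  structure(list(bits = bits), class = "oct_mask")
}

#' @export
print.oct_mask <- function(x, ...) {
  d <- dim(x$bits)
  cat(sprintf("<oct_mask> %d x %d, %.1f%% covered\n", d[1], d[2],
              100 * mean(x$bits)))
  invisible(x)
}

#' @export
dim.oct_mask <- function(x) dim(x$bits)

#' Axial search region
#'
#' Per-lateral-position axial search band `[lo, hi]` (0-based voxel units,
#' inclusive) within which the edge filter is trusted.
#'
#' @param lo,hi Numeric matrices `(Nx, Ny)` with `0 <= lo <= hi <= Nz - 1`.
#' @param nz Axial extent of the volume the region refers to.
#' @return An object of class `oct_region`.
#' @export
oct_region <- function(lo, hi, nz) {
  if (!is.matrix(lo) || !is.matrix(hi) || !all(dim(lo) == dim(hi)))
    stop("`lo` and `hi` must be matrices of equal size", call. = FALSE)
  if (any(lo < 0) || any(hi > nz - 1) || any(lo > hi))
    stop("region bounds must satisfy 0 <= lo <= hi <= Nz - 1", call. = FALSE)
  structure(list(lo = lo, hi = hi, nz = as.integer(nz)), class = "oct_region")
}

#' Whole-depth region
#'
#' Convenience constructor: the search band spans the full axial extent (or
#' `[z_min, Nz - 1]` when a top margin is excluded).
#'
#' @param nx,ny Lateral grid size.
#' @param nz Axial extent.
#' @param z_min Lower bound of the band (0-based), default 0.
#' @return An `oct_region`.
#' @export
full_region <- function(nx, ny, nz, z_min = 0) {
  oct_region(matrix(z_min, nx, ny), matrix(nz - 1, nx, ny), nz)
}

# ---------------------------------------------------------------------------
# Casting
# ---------------------------------------------------------------------------

#' Cast a float32 volume to 8-bit
#'
#' OCT scanners emit 32-bit floats, but their value range already covers the
#' dynamic range of the scan, so the chain processes unsigned 8-bit
#' integers: values are clamped to `[0, 255]` and truncated toward zero,
#' losing only the decimal places. On disk ([write_raw_volume()]) this cuts
#' the footprint to a quarter. Idempotent on already-uint8 volumes.
#'
#' @param v An [oct_volume()].
#' @return An `oct_volume` with `dtype = "uint8"`.
#' @export
cast_to_uint8 <- function(v) {
  stopifnot(inherits(v, "oct_volume"))
  if (v$dtype == "uint8") return(v)
  d <- trunc(pmin(pmax(v$data, 0), 255))
  oct_volume(d, pitch = v$pitch, dtype = "uint8")
}

# ---------------------------------------------------------------------------
# Raw volume I/O: little-endian binary + JSON sidecar.
# File order is A-scan contiguous (z fastest), the natural order in which a
# scanning OCT system emits samples; the sidecar declares dims, dtype, voxel
# pitch, axis order and the z origin.
# ---------------------------------------------------------------------------

#' Read a raw OCT volume
#'
#' Reads a headerless little-endian binary volume described by a JSON sidecar
#' with fields `dims` (`[Nx, Ny, Nz]`), `dtype` (`"uint8"` or `"float32"`),
#' `pitch_um` (3 voxel pitches), `axis_order` (`"zxy"`, z fastest-varying =
#' A-scan contiguous, or `"xyz"`) and `z_origin` (`"top"`). The in-memory
#' volume is always normalized to `(x, y, z)` indexing with z = 0 at the top.
#'
#' @param path Binary volume file.
#' @param meta_path JSON sidecar; defaults to `path` with `.json` appended.
#' @return An [oct_volume()].
#' @export
read_raw_volume <- function(path, meta_path = paste0(path, ".json")) {
  meta <- jsonlite::fromJSON(meta_path)
  for (f in c("dims", "dtype", "pitch_um"))
    if (is.null(meta[[f]]))
      stop(sprintf("sidecar missing field '%s'", f), call. = FALSE)
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("sidecar dims must be 3 positive integers", call. = FALSE)
  axis_order <- if (is.null(meta$axis_order)) "zxy" else meta$axis_order
  if (!axis_order %in% c("zxy", "xyz"))
    stop(sprintf("unknown axis_order '%s'", axis_order), call. = FALSE)
  if (!is.null(meta$z_origin) && !identical(meta$z_origin, "top"))
    stop("only z_origin = \"top\" volumes are supported", call. = FALSE)
  n <- prod(dims)
  bpv <- switch(meta$dtype, uint8 = 1L, float32 = 4L,
                stop(sprintf("unknown dtype '%s'", meta$dtype), call. = FALSE))
  sz <- file.size(path)
  if (is.na(sz) || sz != n * bpv)
    stop(sprintf("file length %s does not match %d x %d x %d %s voxels",
                 sz, dims[1], dims[2], dims[3], meta$dtype), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- if (meta$dtype == "uint8") {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                       endian = "little"))
  } else {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  }
  arr <- if (axis_order == "zxy") {
    aperm(array(raw, dim = dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  } else {
    array(raw, dim = dims)
  }
  oct_volume(arr, pitch = meta$pitch_um, dtype = meta$dtype)
}

#' Write a raw OCT volume
#'
#' Inverse of [read_raw_volume()]: little-endian binary, A-scan contiguous
#' (z fastest), plus JSON sidecar. Round trips are bit-exact for uint8
#' payloads.
#'
#' @param v An [oct_volume()].
#' @param path Output binary file.
#' @param meta_path JSON sidecar path; defaults to `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_raw_volume <- function(v, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(v, "oct_volume"))
  d <- dim(v$data)
  vec <- as.vector(aperm(v$data, c(3L, 1L, 2L)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (v$dtype == "uint8") {
    writeBin(as.integer(vec), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(vec), con, size = 4L, endian = "little")
  }
  meta <- list(dims = d, dtype = v$dtype, pitch_um = v$pitch,
               axis_order = "zxy", z_origin = "top")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Surface / mask / image I/O
# ---------------------------------------------------------------------------

#' Write a surface heightmap
#'
#' 16-bit grayscale TIFF. Defined heights are affinely mapped to the code
#' range `[1, 65535]`; code 0 is reserved for holes. The scale (`h_min`,
#' `h_max`, hole convention, `nz`, pitch) is recorded in a JSON sidecar so
#' [read_surface()] restores fractional heights to within 1/65535 of the
#' height range.
#'
#' @param s An [oct_surface()].
#' @param path Output TIFF file.
#' @param meta_path JSON sidecar path; defaults to `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(s, "oct_surface"))
  h <- s$heights
  def <- !is.na(h)
  if (!any(def)) stop("cannot write an all-hole surface", call. = FALSE)
  h_min <- min(h[def]); h_max <- max(h[def])
  rng <- if (h_max > h_min) h_max - h_min else 1
  code <- matrix(0, nrow(h), ncol(h))
  code[def] <- 1 + round((h[def] - h_min) / rng * 65534)
  # writeTIFF expects [0,1] row-major (y, x): transpose the (x, y) grid
  tiff::writeTIFF(t(code) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(h_min = h_min, h_max = h_max, nz = s$nz, pitch_um = s$pitch,
               hole_code = 0, has_holes = any(!def))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a surface heightmap written by [write_surface()]
#'
#' @param path TIFF file.
#' @param meta_path JSON sidecar path.
#' @return An [oct_surface()].
#' @export
read_surface <- function(path, meta_path = paste0(path, ".json")) {
  meta <- jsonlite::fromJSON(meta_path)
  img <- tiff::readTIFF(path)
  code <- round(t(img) * 65535)
  rng <- if (meta$h_max > meta$h_min) meta$h_max - meta$h_min else 1
  h <- meta$h_min + (code - 1) / 65534 * rng
  h[code == 0] <- NA_real_
  h[!is.na(h)] <- pmin(pmax(h[!is.na(h)], 0), meta$nz - 1)
  oct_surface(h, nz = meta$nz, pitch = meta$pitch_um)
}

#' Write a fingertip mask as an 8-bit PNG (255 = fingertip)
#'
#' @param m An [oct_mask()].
#' @param path Output PNG file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "oct_mask"))
  png::writePNG(t(m$bits) * 1.0, path)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#'
#' @param path PNG file.
#' @return An [oct_mask()].
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  oct_mask(t(img) > 0.5)
}

#' Write a 2D grayscale fingerprint image
#'
#' 8-bit PNG; values in `[0, 1]`, ridges dark, background white. The image
#' resolution (ppi) derived from the lateral pitch is recorded as PNG dpi
#' metadata.
#'
#' @param fp A `fingerprint_2d` object from [project_2d()], or a numeric
#'   matrix in `[0, 1]`.
#' @param path Output PNG file.
#' @return `path`, invisibly.
#' @export
write_image <- function(fp, path) {
  if (inherits(fp, "fingerprint_2d")) {
    px <- fp$pixels
    dpi <- fp$ppi
  } else {
    px <- fp
    dpi <- NULL
  }
  px <- pmin(pmax(px, 0), 1)
  png::writePNG(t(px), path, dpi = dpi)
  invisible(path)
}

# internal: clamp helper shared across modules
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
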