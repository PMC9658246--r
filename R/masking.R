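# ---------------------------------------------------------------------------
# Fingertip masking: classify which lateral positions are covered by the
# fingertip, from intensity contrast across the outer surface.
# ---------------------------------------------------------------------------

#' Masking configuration
#'
#' @param w_n Half-depth (voxels) of the probe bands above and below the
#'   outer surface; default 20, the expected outer-layer thickness at full
#'   resolution.
#' @param ridge_px Expected pixel distance between friction ridges (box-blur
#'   kernel size), odd and `>= 3`. The default 25 corresponds to a ~500 um
#'   ridge period at 20 um lateral pitch.
#' @return An object of class `masking_config`.
#' @export
masking_config <- function(w_n = 20, ridge_px = 25) {
  if (w_n < 1) stop("w_n must be >= 1", call. = FALSE)
  if (ridge_px < 3 || ridge_px %% 2 != 1)
    stop("ridge_px must be odd and >= 3", call. = FALSE)
  structure(list(w_n = as.integer(w_n), ridge_px = as.integer(ridge_px)),
            class = "masking_config")
}

#' Raw fingertip mask from above/below intensity contrast
#'
#' The outer fingerprint sits exactly at the air-skin boundary, so for scan
#' lines covered by the fingertip the maximum voxel value just below the
#' surface (skin) far exceeds the maximum just above it (air). Each lateral
#' position compares `max V` over `z in (S, S + w_n]` against `max V` over
#' `z in [S - w_n, S)`; the bit is set when below > above (ties break to
#' background, biasing against false fingerprint area). Bands are clipped at
#' the volume bounds. Over uncovered background the comparison is a coin
#' flip, which [refine_mask()] cleans up.
#'
#' @param v An [oct_volume()].
#' @param s The outer [oct_surface()], hole-free over the scan area.
#' @param w_n Probe band depth in voxels (`< Nz`).
#' @return An [oct_mask()] (raw, unrefined).
#' @export
raw_mask <- function(v, s, w_n = 20) {
  stopifnot(inherits(v, "oct_volume"), inherits(s, "oct_surface"))
  d <- dim(v$data)
  if (w_n >= d[3]) stop("w_n must be smaller than the volume depth",
                        call. = FALSE)
  if (anyNA(s$heights))
    stop("surface must be hole-free for masking", call. = FALSE)
  nz <- d[3]; m <- d[1] * d[2]
  smat <- matrix(aperm(v$data, c(3L, 1L, 2L)), nz, m)
  iz <- as.integer(floor(as.vector(s$heights))) + 1L  # voxel containing S
  below <- rep(-Inf, m); above <- rep(-Inf, m)
  cols <- seq_len(m)
  for (k in seq_len(w_n)) {
    zb <- iz + k
    ok <- zb <= nz
    below[ok] <- pmax(below[ok], smat[cbind(zb[ok], cols[ok])])
    za <- iz - k
    ok <- za >= 1L
    above[ok] <- pmax(above[ok], smat[cbind(za[ok], cols[ok])])
  }
  oct_mask(matrix(below > above, d[1], d[2]))
}

# internal: 4-connected component labels of a logical matrix (0 = FALSE
# pixels). Deterministic: components are numbered in column-major order of
# their first pixel.
label4 <- function(b) {
  nx <- nrow(b); ny <- ncol(b)
  lab <- matrix(0L, nx, ny)
  nextlab <- 0L
  repeat {
    seed <- which(b & lab == 0L)
    if (!length(seed)) break
    seed <- seed[1L]
    nextlab <- nextlab + 1L
    frontier <- seed
    lab[frontier] <- nextlab
    while (length(frontier)) {
      i <- (frontier - 1L) %% nx + 1L
      j <- (frontier - 1L) %/% nx + 1L
      cand <- c(frontier[i > 1L] - 1L, frontier[i < nx] + 1L,
                frontier[j > 1L] - nx, frontier[j < ny] + nx)
      cand <- unique(cand[b[cand] & lab[cand] == 0L])
      lab[cand] <- nextlab
      frontier <- cand
    }
  }
  lab
}

# internal: fill interior holes and keep the largest 4-connected TRUE
# component; exterior = FALSE region 4-connected to the image border
solidify_mask <- function(bits) {
  nx <- nrow(bits); ny <- ncol(bits)
  lab_bg <- label4(!bits)
  border <- c(lab_bg[1, ], lab_bg[nx, ], lab_bg[, 1], lab_bg[, ny])
  ext <- unique(border[border > 0L])
  bits[!bits & !(lab_bg %in% ext)] <- TRUE    # interior spots -> fingertip
  lab_fg <- label4(bits)
  if (max(lab_fg) == 0L)
    abort_processing("no fingertip found in the scan")
  sizes <- tabulate(lab_fg[lab_fg > 0L])
  keep <- which.max(sizes)                    # ties: first (deterministic)
  lab_fg == keep
}

#' Refine a raw mask into a single solid fingertip region
#'
#' The raw above/below mask is correct inside the fingertip but random over
#' the background. Refinement blurs the 0/1 field with a box filter sized to
#' the ridge distance (averaging away the coin-flip background), re-binarizes
#' with Otsu's adaptive threshold, flood-fills from the image border to
#' identify the contiguous exterior (4-connected, so thin diagonal leaks do
#' not merge regions), flips interior spots to fingertip and clears exterior
#' spots, and finally smooths the contour with one more blur + re-binarize
#' pass. The result is a single 4-connected component with no interior holes.
#'
#' @param raw A [raw_mask()] result.
#' @param ridge_px Box-blur kernel size (odd).
#' @return The final [oct_mask()].
#' @export
refine_mask <- function(raw, ridge_px = 25) {
  stopifnot(inherits(raw, "oct_mask"))
  if (!any(raw$bits)) abort_processing("raw mask is empty")
  r <- (as.integer(ridge_px) - 1L) %/% 2L
  blur <- box_mean(raw$bits * 1, r)
  if (max(blur) - min(blur) < 1e-12)
    abort_processing("no fingertip found (uniform mask field)")
  thr <- EBImage::otsu(EBImage::Image(blur), range = c(0, 1))
  bits <- solidify_mask(blur > thr)
  # contour smoothing: one blur + re-binarize pass, then re-solidify so the
  # single-component/no-hole invariant survives
  bits <- solidify_mask(box_mean(bits * 1, r) > 0.5)
  oct_mask(bits)
}

#' Dice overlap between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b [oct_mask()] objects (or logical matrices) of equal size.
#' @return Dice coefficient in `[0, 1]`.
#' @export
mask_dice <- function(a, b) {
  ba <- if (inherits(a, "oct_mask")) a$bits else a
  bb <- if (inherits(b, "oct_mask")) b$bits else b
  stopifnot(all(dim(ba) == dim(bb)))
  denom <- sum(ba) + sum(bb)
  if (denom == 0) return(1)
  2 * sum(ba & bb) / denom
}

#' Largest centered square fully inside a mask
#'
#' Finds the largest axis-aligned square, centered at the mask centroid,
#' whose pixels are all covered. Useful for spectral measurements that must
#' avoid the mask contour.
#'
#' @param m An [oct_mask()].
#' @return List with index vectors `x`, `y` (and `half`, the half-size).
#' @export
mask_inscribed_square <- function(m) {
  stopifnot(inherits(m, "oct_mask"))
  b <- m$bits
  if (!any(b)) stop("empty mask", call. = FALSE)
  ij <- which(b, arr.ind = TRUE)
  cx <- round(mean(ij[, 1])); cy <- round(mean(ij[, 2]))
  half <- 0L
  repeat {
    h2 <- half + 1L
    xs <- (cx - h2):(cx + h2); ys <- (cy - h2):(cy + h2)
    if (min(xs) < 1L || min(ys) < 1L || max(xs) > nrow(b) ||
        max(ys) > ncol(b) || !all(b[xs, ys])) break
    half <- h2
  }
  list(x = (cx - half):(cx + half), y = (cy - half):(cy + half),
       half = half)
}
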