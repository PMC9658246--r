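# ---------------------------------------------------------------------------
# Envelope-based volume flattening / unflattening and the 3D-to-2D
# conversion of a segmented fingerprint surface.
# ---------------------------------------------------------------------------

#' Flatten a volume against the outer-fingerprint envelope
#'
#' Every scan line is shifted toward the scan top by
#' `E_S(x, y) + delta_S`, where `delta_S = max over mask of (S - E_S)` is the
#' height of the outer fingerprint layer; the shift discards everything at or
#' above the outer surface, guaranteeing its complete removal so it cannot
#' interfere with the inner-fingerprint pass, while bringing the
#' dermal-epidermal junction close to the volume top. Flattening always
#' references the smooth envelope, never the ridged surface itself: shifting
#' by the surface would imprint the outer ridge pattern onto the lower skin
#' layers and produce a hybrid fingerprint. Samples shifted past the top are
#' discarded, vacated bottom samples zero-filled. Shifts are rounded to
#' whole voxels (no axial resampling) and recorded for exact reversal.
#'
#' Outside the mask the envelope is extrapolated by outward propagation from
#' the masked area (8-neighbor mean, deterministic) and those lines are
#' flagged in the record.
#'
#' @param v The [oct_volume()] to flatten.
#' @param s The outer [oct_surface()], hole-free inside the mask.
#' @param e_s Its [upper_envelope()] (`E_S`).
#' @param m The fingertip [oct_mask()].
#' @param snap Quantum (voxels) for the global truncation offset:
#'   `delta_S` is rounded UP to the next multiple of `snap`. Snapping to the
#'   axial block size of the downstream volume pyramid (`2^N`) keeps the
#'   flattened grid aligned with the pyramid decomposition and makes the
#'   inner-fingerprint pass insensitive to small changes in the estimated
#'   outer-layer thickness; 1 disables snapping.
#' @return List with `volume` (the flattened [oct_volume()]) and `record`
#'   (class `flatten_record`: integer `shift` grid, scalar `delta_s` — the
#'   exact `max(S - E_S)` —, integer `delta_applied`, logical
#'   `extrapolated` grid).
#' @export
flatten_volume <- function(v, s, e_s, m, snap = 1L) {
  stopifnot(inherits(v, "oct_volume"), inherits(s, "oct_surface"),
            inherits(e_s, "oct_surface"), inherits(m, "oct_mask"))
  bits <- m$bits
  if (!any(bits)) stop("empty mask", call. = FALSE)
  if (anyNA(s$heights[bits]) || anyNA(e_s$heights[bits]))
    stop("surface and envelope must be hole-free inside the mask",
         call. = FALSE)
  d <- dim(v$data)
  nz <- d[3]
  delta_s <- max(s$heights[bits] - e_s$heights[bits])
  delta_s <- max(delta_s, 0)
  es_full <- e_s$heights
  es_full[!bits] <- NA_real_
  es_full <- fill_matrix_holes(es_full)      # outward extrapolation
  # decompose the shift into a per-line part (the envelope, rounded) and a
  # global integer truncation offset (the outer-layer height, rounded up so
  # removal stays complete). Keeping the global part a shared integer makes
  # the inner-fingerprint pass robust to small changes in the outer-layer
  # thickness estimate: the flattened volume moves as a whole instead of
  # acquiring a per-line rounding pattern.
  delta_applied <- as.integer(ceiling(delta_s / snap) * snap)
  shift <- as.integer(clamp(round(es_full) + delta_applied, 0, nz))
  smat <- matrix(aperm(v$data, c(3L, 1L, 2L)), nz, d[1] * d[2])
  out <- matrix(0, nz, d[1] * d[2])
  sv <- as.vector(shift)
  for (s0 in unique(sv)) {
    cols <- which(sv == s0)
    if (s0 == 0L) out[, cols] <- smat[, cols]
    else if (s0 < nz)
      out[seq_len(nz - s0), cols] <- smat[(s0 + 1L):nz, cols]
  }
  vol <- oct_volume(aperm(array(out, c(nz, d[1], d[2])), c(2L, 3L, 1L)),
                    pitch = v$pitch, dtype = v$dtype)
  rec <- structure(list(shift = matrix(sv, d[1], d[2]), delta_s = delta_s,
                        delta_applied = delta_applied,
                        extrapolated = !bits, nz = nz),
                   class = "flatten_record")
  list(volume = vol, record = rec)
}

#' Reverse flattening shifts on a surface
#'
#' Restores the real shape and position of a surface detected in a flattened
#' volume by adding back the recorded per-line integer shifts (the exact
#' inverse of [flatten_volume()]).
#'
#' @param s_flat [oct_surface()] detected in the flattened volume.
#' @param rec The `flatten_record` from the same volume.
#' @return The unflattened [oct_surface()].
#' @export
unflatten_surface <- function(s_flat, rec) {
  stopifnot(inherits(s_flat, "oct_surface"), inherits(rec, "flatten_record"))
  if (!all(dim(s_flat$heights) == dim(rec$shift)))
    stop("surface and flatten record dims mismatch", call. = FALSE)
  oct_surface(clamp(s_flat$heights + rec$shift, 0, rec$nz - 1),
              nz = rec$nz, pitch = s_flat$pitch)
}

#' Convert a 3D fingerprint surface to a 2D grayscale fingerprint
#'
#' Parallel projection: the surface is flattened against its upper envelope
#' and the remaining undulation normalized by the local envelope separation
#' to compensate natural ridge-height variation,
#' `FP2D = clamp((S - Eup) / (Elow - Eup), 0, 1)`. Ridge tops (`S = Eup`)
#' map to 0 (dark), valley bottoms to 1, matching conventional fingerprint
#' imagery; degenerate pixels (`Elow - Eup` below `eps`) carry no relief and
#' map to 0.5; everything outside the mask is background white (1).
#'
#' @param s The fingerprint [oct_surface()].
#' @param eup,elow Its upper and lower envelopes.
#' @param m The fingertip [oct_mask()].
#' @param eps Degeneracy threshold for the envelope separation (voxels).
#' @return An object of class `fingerprint_2d`: `pixels` matrix in `[0, 1]`
#'   and `ppi` metadata derived from the lateral pitch.
#' @export
project_2d <- function(s, eup, elow, m, eps = 1e-6) {
  stopifnot(inherits(s, "oct_surface"), inherits(eup, "oct_surface"),
            inherits(elow, "oct_surface"), inherits(m, "oct_mask"))
  bits <- m$bits
  num <- s$heights - eup$heights
  den <- elow$heights - eup$heights
  px <- clamp(num / den, 0, 1)
  px[!is.na(den) & den < eps] <- 0.5
  px[!bits | is.na(px)] <- 1
  structure(list(pixels = px, ppi = 25400 / s$pitch[1]),
            class = "fingerprint_2d")
}

#' @export
print.fingerprint_2d <- function(x, ...) {
  cat(sprintf("<fingerprint_2d> %d x %d px, %.0f ppi\n",
              nrow(x$pixels), ncol(x$pixels), x$ppi))
  invisible(x)
}

#' Downsample a 2D fingerprint to a target resolution
#'
#' Standard minutiae extractors expect 500 ppi; this resizes the native-grid
#' image (bilinear, via [EBImage::resize()]) and updates the metadata.
#'
#' @param fp A `fingerprint_2d`.
#' @param ppi Target resolution, default 500.
#' @return A resized `fingerprint_2d`.
#' @export
resample_fingerprint <- function(fp, ppi = 500) {
  stopifnot(inherits(fp, "fingerprint_2d"))
  f <- ppi / fp$ppi
  w <- max(2L, round(nrow(fp$pixels) * f))
  h <- max(2L, round(ncol(fp$pixels) * f))
  px <- EBImage::imageData(EBImage::resize(EBImage::Image(fp$pixels), w, h))
  structure(list(pixels = clamp(px, 0, 1), ppi = ppi),
            class = "fingerprint_2d")
}

#' Dominant ridge spatial frequency of a 2D fingerprint
#'
#' Locates the strongest non-DC peak of the 2D power spectrum inside the
#' mask, restricted to spatial periods between `period_range` pixels (the
#' plausible ridge-period band, excluding the finger-shape low frequencies).
#' Used to verify that outer and inner fingerprints share the same ridge
#' pattern.
#'
#' @param fp A `fingerprint_2d` or a numeric matrix.
#' @param m Optional [oct_mask()]; outside pixels are replaced by the masked
#'   mean before the transform.
#' @param period_range Numeric length-2, admissible period band in pixels.
#' @return Dominant spatial frequency in cycles/pixel.
#' @export
ridge_frequency <- function(fp, m = NULL, period_range = c(4, 64)) {
  px <- if (inherits(fp, "fingerprint_2d")) fp$pixels else fp
  if (!is.null(m)) {
    mu <- mean(px[m$bits])
    px[!m$bits] <- mu
  }
  px <- px - mean(px)
  P <- Mod(stats::fft(px))^2
  nx <- nrow(px); ny <- ncol(px)
  fx <- (seq_len(nx) - 1) / nx
  fx <- ifelse(fx > 0.5, fx - 1, fx)
  fy <- (seq_len(ny) - 1) / ny
  fy <- ifelse(fy > 0.5, fy - 1, fy)
  fmag <- sqrt(outer(fx^2, fy^2, "+"))
  band <- fmag >= 1 / period_range[2] & fmag <= 1 / period_range[1]
  if (!any(band)) stop("period band outside the spectrum", call. = FALSE)
  fmag[which.max(P * band)]
}

#' Spectral power in the ridge-frequency band
#'
#' Total 2D power within a relative bandwidth around a given spatial
#' frequency, computed on a Hann-windowed, mean-removed matrix. Used to
#' quantify how much ridge information a surface (or envelope) carries: a
#' valid ridge envelope retains the finger shape but almost none of the
#' ridge-band power of the surface it envelops.
#'
#' @param mat Numeric matrix (e.g. a surface crop from
#'   [mask_inscribed_square()]).
#' @param f0 Center frequency in cycles/pixel.
#' @param rel_bw Relative half-bandwidth (default 0.25).
#' @return Summed power in the band.
#' @export
ridge_band_power <- function(mat, f0, rel_bw = 0.25) {
  nx <- nrow(mat); ny <- ncol(mat)
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nx) - 1) / (nx - 1)))
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(ny) - 1) / (ny - 1)))
  w <- outer(wx, wy)
  P <- Mod(stats::fft((mat - mean(mat)) * w))^2
  fx <- (seq_len(nx) - 1) / nx; fx <- ifelse(fx > 0.5, fx - 1, fx)
  fy <- (seq_len(ny) - 1) / ny; fy <- ifelse(fy > 0.5, fy - 1, fy)
  fm <- sqrt(outer(fx^2, fy^2, "+"))
  sum(P[abs(fm - f0) < rel_bw * f0])
}
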