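# ---------------------------------------------------------------------------
# Preprocessing: intensity roll-off compensation, the 3D volume pyramid, and
# multiplicative contrast enhancement.
# ---------------------------------------------------------------------------

#' Compensate the depth-dependent intensity roll-off
#'
#' OCT sensitivity declines with depth, so on a curved fingertip the parts
#' farther from the scan head are dimmer. The compensation measures the mean
#' intensity of every en-face slice, `A(z)`, fits an ordinary least-squares
#' line through it, and subtracts the line's deviation
#' `delta(z) = Ahat(z) - mean(A)` from every voxel at depth z, artificially
#' amplifying the deeper layers. Results are clamped to the dtype range.
#' For uint8 volumes the correction is quantized to whole intensity steps,
#' so the compensation never re-quantizes the data: voxel values change by
#' exactly the per-depth step, and a volume without roll-off is returned
#' unchanged to within one intensity step.
#'
#' @param v An [oct_volume()] with `Nz >= 8`.
#' @return The compensated `oct_volume`.
#' @export
rolloff_compensate <- function(v) {
  stopifnot(inherits(v, "oct_volume"))
  d <- dim(v$data)
  if (d[3] < 8) stop("volume too shallow for roll-off regression",
                     call. = FALSE)
  nz <- d[3]
  A <- colMeans(matrix(v$data, d[1] * d[2], nz))
  z <- seq_len(nz) - 1
  zc <- z - mean(z)
  a <- sum(zc * A) / sum(zc * zc)           # OLS slope
  delta <- a * zc                           # Ahat(z) - mean(A)
  if (v$dtype == "uint8") delta <- round(delta)
  out <- v$data - rep(delta, each = d[1] * d[2])
  if (v$dtype == "uint8") out <- clamp(out, 0, 255)
  oct_volume(out, pitch = v$pitch, dtype = v$dtype)
}

# internal: 2x trilinear (block-average) reduction of a 3D array.
# Center-aligned linear interpolation at half-voxel offsets reduces exactly
# to the mean of each 2x2x2 block.
downsample2 <- function(a) {
  d <- dim(a)
  i1 <- seq(1L, d[1], 2L)
  a <- a[i1, , , drop = FALSE] + a[i1 + 1L, , , drop = FALSE]
  d <- dim(a)
  j1 <- seq(1L, d[2], 2L)
  a <- a[, j1, , drop = FALSE] + a[, j1 + 1L, , drop = FALSE]
  d <- dim(a)
  k1 <- seq(1L, d[3], 2L)
  (a[, , k1, drop = FALSE] + a[, , k1 + 1L, drop = FALSE]) / 8
}

# internal: index/weight pair for 2x center-aligned upsampling of one axis.
# Fine sample xf (1-based) reads the coarse field at xc = xf/2 + 1/4, i.e.
# slightly offset from the coarse voxel centers; edges clamp.
up2_index <- function(n_coarse) {
  xf <- seq_len(2L * n_coarse)
  xc <- xf / 2 + 0.25
  lo <- clamp(floor(xc), 1, n_coarse)
  hi <- clamp(lo + 1, 1, n_coarse)
  w <- xc - floor(xc)                       # weight of hi
  list(lo = as.integer(lo), hi = as.integer(hi), w = w)
}

# internal: 2x trilinear upsampling of a 3D array (separable, center-aligned
# with half-voxel offset sampling). Constant input stays exactly constant,
# so no cluster/edge artifacts are introduced.
upsample2 <- function(a) {
  for (ax in 1:3) {
    d <- dim(a)
    ix <- up2_index(d[ax])
    a <- switch(ax,
      a[ix$lo, , , drop = FALSE] * (1 - ix$w) +
        a[ix$hi, , , drop = FALSE] * ix$w,
      a[, ix$lo, , drop = FALSE] * rep(1 - ix$w, each = d[1]) +
        a[, ix$hi, , drop = FALSE] * rep(ix$w, each = d[1]),
      a[, , ix$lo, drop = FALSE] *
        rep(1 - ix$w, each = d[1] * d[2]) +
        a[, , ix$hi, drop = FALSE] * rep(ix$w, each = d[1] * d[2]))
  }
  a
}

#' Build a multi-resolution volume pyramid
#'
#' Level 0 is the input; each further level halves all three dimensions by
#' trilinear (center-aligned block-average) reduction, which suppresses
#' speckle without changing the aspect ratio of the finger.
#'
#' @param v An [oct_volume()] whose dimensions are divisible by `2^N`.
#' @param N Number of additional levels (`N >= 1`).
#' @return An object of class `volume_pyramid`: list with `levels`
#'   (volumes `V0 .. VN`) and `N`.
#' @export
build_pyramid <- function(v, N) {
  stopifnot(inherits(v, "oct_volume"))
  N <- as.integer(N)
  if (N < 1) stop("pyramid depth N must be >= 1", call. = FALSE)
  d <- dim(v$data)
  if (any(d %% 2^N != 0))
    stop(sprintf("dims %s not divisible by 2^%d", paste(d, collapse = "x"), N),
         call. = FALSE)
  levels <- vector("list", N + 1L)
  levels[[1L]] <- v
  a <- v$data
  for (n in seq_len(N)) {
    a <- downsample2(a)
    lv <- if (v$dtype == "uint8") round(a) else a
    levels[[n + 1L]] <- oct_volume(lv, pitch = v$pitch * 2^n,
                                   dtype = v$dtype)
  }
  structure(list(levels = levels, N = N), class = "volume_pyramid")
}

#' @export
print.volume_pyramid <- function(x, ...) {
  cat(sprintf("<volume_pyramid> %d levels:\n", x$N + 1L))
  for (i in seq_along(x$levels))
    cat(sprintf("  V%d: %s\n", i - 1L,
                paste(dim(x$levels[[i]]$data), collapse = " x ")))
  invisible(x)
}

#' Multiplicative contrast enhancement of a volume pyramid
#'
#' Up to a certain level of downsampling, the coarse volumes represent the
#' macrostructure of the fingerprint more reliably than their full-resolution
#' counterparts. Starting at the coarsest level, each volume is trilinearly
#' upsampled (at positions slightly offset from the coarse voxel centers,
#' which avoids the cluster/edge artifacts of simple value doubling) and
#' voxel-wise multiplied into its finer predecessor; the product is
#' normalized back to the intensity range `[0, 255]` to avoid overflow, by
#' taking its square root — the geometric mean of the two pyramid levels.
#' The geometric mean is content-independent (no global rescaling
#' constants), so enhancement at one lateral position never depends on
#' voxels elsewhere in the scan, keeping segmentation reproducible under
#' local changes to the volume. It embeds the reliable macrostructure into
#' the high-resolution volumes without sacrificing accuracy where no
#' enhancement is needed: voxels whose coarse and fine values agree keep
#' their value, voxels that disagree across scales are pulled toward the
#' dimmer of the two.
#'
#' @param p A [build_pyramid()] result.
#' @return The modified `volume_pyramid`.
#' @export
contrast_enhance <- function(p) {
  stopifnot(inherits(p, "volume_pyramid"))
  for (i in seq(p$N + 1L, 2L)) {
    u <- upsample2(p$levels[[i]]$data)
    out <- sqrt(pmax(p$levels[[i - 1L]]$data * u, 0))
    if (p$levels[[i - 1L]]$dtype == "uint8") out <- round(out)
    p$levels[[i - 1L]]$data <- out
  }
  p
}
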