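# ---------------------------------------------------------------------------
# Adaptive 1D low-pass edge detection filter.
#
# The dense kernel family for even size L:
#   k0 = [1, 2, ..., L/2, -L/2, ..., -2, -1]          (length L)
#   k1 = [1, 1, ..., 1, -L, 1, ..., 1, 1]             (length L + 1)
#   k2 = [1, 0, ..., 0, -(L+1), (L+1), 0, ..., 0, -1] (length L + 2)
# k1 is the first difference of the zero-padded k0, k2 that of k1; k2 has
# exactly four non-zero taps regardless of L, so convolving with k2 and
# integrating (cumulatively summing) twice reproduces the k0 response in a
# single O(Nz) pass whose cost is independent of the kernel size.
#
# Normalization (2/L) / (L/2 + 1) equalizes the peak response on a unit step
# across kernel sizes (peak value 1/2 for every even L), so responses of
# different kernels are directly comparable.
# ---------------------------------------------------------------------------

#' Construct the edge-detection kernel family for size L
#'
#' Builds the dense kernel, its first derivative, and the 4-tap sparse second
#' derivative, together with the normalization constant
#' `(2/L) / (L/2 + 1)`. All three kernels sum to zero, so constant scan lines
#' produce identically zero response.
#'
#' @param L Even kernel size, `L >= 2`.
#' @return An object of class `kernel_family` with elements `L`, `taps0`,
#'   `taps1`, `taps2`, `norm`, and `scale` (the factor actually applied
#'   during convolution; 1 until [normalize_kernels()] is called).
#' @export
make_kernels <- function(L) {
  if (length(L) != 1L || !is.finite(L) || L < 2 || L %% 2 != 0)
    stop("kernel size L must be a single even integer >= 2", call. = FALSE)
  L <- as.integer(L)
  h <- L %/% 2L
  taps0 <- c(seq_len(h), -rev(seq_len(h)))
  taps1 <- c(rep(1, h), -L, rep(1, h))
  taps2 <- c(1, rep(0, h - 1L), -(L + 1), L + 1, rep(0, h - 1L), -1)
  structure(list(L = L, taps0 = taps0, taps1 = taps1, taps2 = taps2,
                 norm = (2 / L) / (L / 2 + 1), scale = 1,
                 normalized = FALSE),
            class = "kernel_family")
}

#' Normalize a kernel family
#'
#' Multiplies every tap by `(2/L) / (L/2 + 1)` so that the peak response of
#' the dense kernel on a unit step is 1/2 for any kernel size, making filter
#' responses comparable across sizes.
#'
#' @param k A [make_kernels()] family.
#' @return The normalized `kernel_family`.
#' @export
normalize_kernels <- function(k) {
  stopifnot(inherits(k, "kernel_family"))
  if (k$normalized) return(k)
  k$taps0 <- k$taps0 * k$norm
  k$taps1 <- k$taps1 * k$norm
  k$taps2 <- k$taps2 * k$norm
  k$scale <- k$norm
  k$normalized <- TRUE
  k
}

#' @export
print.kernel_family <- function(x, ...) {
  cat(sprintf("<kernel_family> L = %d, %snormalized (norm = %.6g)\n",
              x$L, if (x$normalized) "" else "not ", x$norm))
  invisible(x)
}

#' Edge-filter response of one scan line via sparse convolution
#'
#' Computes the zero-padded convolution of the (optionally normalized) dense
#' kernel with a scan line, by convolving with the 4-tap sparse kernel and
#' cumulatively summing twice; the double integration cancels the second
#' derivative while the zero- and first-order kernels contribute only the
#' integration constants. With zero padding and `z0 = 0` both constants
#' vanish and a single forward pass suffices; for `z0 > 0` the constants
#' `(k1 * s)(z0)` and `(k0 * s)(z0)` are evaluated directly and the response
#' is integrated forward from there (positions before `z0` are `NA`).
#'
#' Alignment: the returned vector `r` satisfies `r[z + 1] = full[z + L/2]`
#' where `full` is the 1-based full zero-padded convolution, chosen so that
#' an ideal step at 0-based index `j` peaks exactly at `r[j + 1]`.
#'
#' @param line Numeric scan line (length `>= L + 2`).
#' @param k A `kernel_family`.
#' @param z0 Start index for the integration constants (0-based), default 0.
#' @return Numeric response, one value per sample of `line`.
#' @export
sparse_convolve <- function(line, k, z0 = 0) {
  stopifnot(inherits(k, "kernel_family"))
  line <- as.numeric(line)
  nz <- length(line)
  L <- k$L
  if (nz < L + 2) stop("scan line shorter than kernel support", call. = FALSE)
  if (z0 < 0 || z0 > nz - 1) stop("z0 outside the scan line", call. = FALSE)
  if (z0 == 0)
    return(edge_response_cpp(matrix(line, ncol = 1L), L, k$scale)[, 1])
  h <- L %/% 2L
  # full-convolution coordinate of output position z (0-based): n = z + h - 1
  conv_at <- function(taps, n) {
    p <- seq_along(taps) - 1L           # 0-based tap positions
    i <- n - p                          # 0-based signal indices
    ok <- i >= 0L & i <= nz - 1L
    sum(taps[ok] * line[i[ok] + 1L])
  }
  n0 <- z0 + h - 1L
  c0 <- conv_at(k$taps0, n0)
  c1 <- conv_at(k$taps1, n0)
  # sparse second-derivative response over the needed full-coordinate range
  nmax <- (nz - 1L) + h - 1L
  full2 <- function(n) {
    v <- numeric(length(n))
    for (ofs in list(c(0L, 1), c(h, -(L + 1)), c(h + 1L, L + 1),
                     c(L + 1L, -1))) {
      i <- n - ofs[1]
      ok <- i >= 0L & i <= nz - 1L
      v[ok] <- v[ok] + ofs[2] * line[i[ok] + 1L]
    }
    v * k$scale
  }
  out <- rep(NA_real_, nz)
  out[z0 + 1L] <- c0
  if (n0 < nmax) {
    ns <- (n0 + 1L):nmax
    r2 <- full2(ns)
    # r0(n) = c0 + c1 (n - n0) + sum_{a = n0+1..n} (n - a + 1) r2(a)
    s1 <- cumsum(r2)
    s2 <- cumsum(s1)
    zs <- (z0 + 1L):(nz - 1L)
    out[zs + 1L] <- c0 + c1 * (zs - z0) + s2[zs - z0]
  }
  out
}

#' Peak edge response of one scan line within a search band
#'
#' Restricts the filter response to the axial region `[z_lo, z_hi]`, finds
#' the maximum, and applies the validity gate: the position is accepted only
#' if the response declines to `<= 0` within `L` samples on both sides of
#' the maximum (a mismatched kernel smears the edge and fails this).
#' Accepted peaks are refined to sub-voxel precision by parabolic
#' interpolation through the three samples around the discrete maximum.
#'
#' @param line Numeric scan line.
#' @param k A `kernel_family` (use a normalized family when comparing
#'   responses across kernel sizes).
#' @param region Length-2 numeric, 0-based inclusive band `c(z_lo, z_hi)`.
#' @return List with `position` (fractional 0-based index, or `NA` if the
#'   gate rejects the peak) and `response` (the peak filter response within
#'   the band, clamped at 0; kept for diagnostics even when invalid).
#' @export
line_edge_response <- function(line, k, region = c(0, length(line) - 1)) {
  stopifnot(inherits(k, "kernel_family"))
  line <- as.numeric(line)
  if (length(region) != 2L || region[1] > region[2])
    stop("empty search region", call. = FALSE)
  res <- detect_lines_cpp(matrix(line, ncol = 1L), k$L, k$scale,
                          as.integer(floor(region[1])),
                          as.integer(ceiling(region[2])), TRUE)
  list(position = res$pos[1], response = res$wt[1])
}

# internal: response matrix for a whole stack of scan lines (Nz x M)
edge_response_matrix <- function(smat, k) {
  edge_response_cpp(smat, k$L, k$scale)
}
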