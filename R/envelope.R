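# ---------------------------------------------------------------------------
# Ridge envelopes: smooth heightmaps touching only the ridge tops (upper) or
# valley bottoms (lower). They carry the finger shape but no ridge detail,
# which is exactly what volume flattening needs.
# ---------------------------------------------------------------------------

#' Envelope configuration
#'
#' @param l Visibility range of the horizon search: the expected maximum
#'   pixel distance between adjacent papillary ridges. Defaults to twice the
#'   masking `ridge_px` (50 px at 20 um pitch).
#' @param smooth_px Final box-filter size (odd), defaults to `ridge_px`.
#' @return An object of class `envelope_config`.
#' @export
envelope_config <- function(l = 50, smooth_px = 25) {
  if (l < 2) stop("l must be >= 2", call. = FALSE)
  if (smooth_px < 1 || smooth_px %% 2 != 1)
    stop("smooth_px must be odd and >= 1", call. = FALSE)
  structure(list(l = as.integer(l), smooth_px = as.integer(smooth_px)),
            class = "envelope_config")
}

#' Upper envelope of a 1D height profile via horizon search
#'
#' Starting at the highest ridge (the global minimum z, since z = 0 is the
#' scan top), the search marches outward in both directions: observed from
#' the current top, the next top is the ridge top within the visibility
#' window `l` that is "observable on the horizon" of the downward-curved
#' surface, i.e. the candidate maximizing the elevation angle toward the
#' scan top (minimizing the signed slope `(h(j) - h(cur)) / |j - cur|`; ties
#' go to the farther sample). Candidates are the local height minima — the
#' ridge tops; without this restriction the march would crawl down the
#' gently-sloped flank of its own ridge wherever the finger curvature is
#' comparable to the ridge slope, and the envelope would retain the ridge
#' pattern it is meant to discard. Minima forming a sharp one-sample "V"
#' (more than 2 z-units below both neighbors) are not credible ridge tops at
#' the scan's lateral resolution — papillary ridges are tens of pixels wide
#' — and are excluded from candidacy, so isolated detection spikes do not
#' pull long tent artifacts into the envelope; the final clip still keeps
#' `env <= profile` pointwise. If the window contains no local minimum
#' (a monotone stretch, e.g. at the profile ends) all samples are eligible,
#' which reduces the step to a bounded convex-hull edge. Positions between
#' consecutive tops are filled by linear interpolation. The envelope never
#' undercuts the profile: `env(z) <= profile(z)` everywhere (in
#' top-direction).
#'
#' @param profile Numeric hole-free height sequence (z units, smaller =
#'   closer to the scan top).
#' @param l Visibility window (`2 <= l <= length(profile) - 1`).
#' @return Numeric envelope of the same length.
#' @export
envelope_1d <- function(profile, l) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (anyNA(profile)) stop("profile must be hole-free", call. = FALSE)
  if (n < 2) return(profile)
  if (l < 2 || l > n - 1)
    stop("visibility window l must be in [2, length - 1]", call. = FALSE)
  # ridge tops: local minima in z (plateaus count, ends compare one-sided);
  # sharp single-sample V minima are detection spikes, not ridge tops
  lmin <- c(profile[1] <= profile[2],
            profile[2:(n - 1)] <= profile[1:(n - 2)] &
              profile[2:(n - 1)] <= profile[3:n],
            profile[n] <= profile[n - 1])
  sharp <- c(FALSE,
             pmin(profile[1:(n - 2)], profile[3:n]) -
               profile[2:(n - 1)] > 2,
             FALSE)
  lmin <- lmin & !sharp
  march <- function(start, dir) {
    tops <- start
    cur <- start
    while ((dir > 0 && cur < n) || (dir < 0 && cur > 1)) {
      reach <- if (dir > 0) min(l, n - cur) else min(l, cur - 1)
      js <- cur + dir * seq_len(reach)
      cand <- js[lmin[js]]
      if (!length(cand)) cand <- js
      slopes <- (profile[cand] - profile[cur]) / abs(cand - cur)
      jnext <- cand[max(which(slopes == min(slopes)))]  # ties -> farther
      tops <- c(tops, jnext)
      cur <- jnext
    }
    tops
  }
  seed <- which.min(profile)
  tops <- c(rev(march(seed, -1L)), march(seed, +1L)[-1L])
  tops <- unique(tops)
  if (length(tops) == 1L) return(rep(profile[tops], n))
  env <- stats::approx(tops, profile[tops], xout = seq_len(n), rule = 2)$y
  # a chord between tops may pass below gently-sloped flank samples that
  # were not eligible as tops; clip so the envelope never undercuts the
  # profile anywhere
  pmin(env, profile)
}

# internal: apply envelope_1d along one axis of a heights matrix, processing
# each contiguous masked run separately (runs of length 1 are copied)
envelope_pass <- function(h, bits, l, along_rows) {
  out <- matrix(NA_real_, nrow(h), ncol(h))
  nlines <- if (along_rows) nrow(h) else ncol(h)
  for (i in seq_len(nlines)) {
    hv <- if (along_rows) h[i, ] else h[, i]
    bv <- if (along_rows) bits[i, ] else bits[, i]
    if (!any(bv)) next
    r <- rle(bv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- rep(NA_real_, length(hv))
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      ev[idx] <- if (length(idx) < 3L) hv[idx]
                 else envelope_1d(hv[idx], min(l, length(idx) - 1L))
    }
    if (along_rows) out[i, ] <- ev else out[, i] <- ev
  }
  out
}

# internal: box blur restricted to the mask (window renormalized to the
# masked area); NA outside
masked_box_mean <- function(vals, bits, smooth_px) {
  r <- (as.integer(smooth_px) - 1L) %/% 2L
  if (r < 1L) return(ifelse(bits, vals, NA_real_))
  v0 <- ifelse(bits, vals, 0)
  num <- box_sum(v0, r)
  den <- box_sum(bits * 1, r)
  out <- num / den
  out[!bits] <- NA_real_
  out
}

# internal: both-direction horizon envelope of a plain heights matrix
# (no smoothing, no class, no height-range checks: also used on mirrored
# surfaces whose values exceed the volume range)
envelope_matrix <- function(h, bits, l) {
  ex <- envelope_pass(h, bits, l, along_rows = TRUE)
  ey <- envelope_pass(h, bits, l, along_rows = FALSE)
  pmin(ex, ey)                           # closest to the topside wins
}

#' Upper ridge envelope of a fingerprint surface
#'
#' Runs the horizon search of [envelope_1d()] along every B-scan row and,
#' because shallow crossings of diagonal ridges let a single pass dip into
#' the valleys, again along every column; the two preliminary surfaces are
#' combined per pixel by taking the one closest to the scan top (smallest
#' z — the errors of the two passes do not coincide). A final box filter
#' removes the roughness left by diagonal ridges and skin imperfections.
#'
#' @param s An [oct_surface()], hole-free inside the mask.
#' @param m An [oct_mask()]; the envelope is undefined (`NA`) outside.
#' @param cfg An [envelope_config()].
#' @param smooth Apply the final box filter (set `FALSE` to inspect the raw
#'   interpolated envelope, which touches the ridge tops exactly).
#' @return The envelope as an [oct_surface()].
#' @export
upper_envelope <- function(s, m, cfg = envelope_config(), smooth = TRUE) {
  stopifnot(inherits(s, "oct_surface"), inherits(m, "oct_mask"))
  if (!any(m$bits)) stop("empty mask", call. = FALSE)
  if (anyNA(s$heights[m$bits]))
    stop("surface must be hole-free inside the mask", call. = FALSE)
  e <- envelope_matrix(s$heights, m$bits, cfg$l)
  if (smooth) {
    # the box filter pulls the envelope below the ridge tops wherever the
    # finger curves (mean of a convex depth profile exceeds its center
    # value); re-clip to the surface so the defining bound Eup <= S
    # survives smoothing
    e <- pmin(masked_box_mean(e, m$bits, cfg$smooth_px), s$heights)
  }
  oct_surface(clamp(e, 0, s$nz - 1), nz = s$nz, pitch = s$pitch)
}

#' Lower ridge envelope (valley bottoms)
#'
#' Computed with the same horizon search, applied to a version of the
#' surface vertically mirrored at the upper envelope (which swaps peaks and
#' valleys), then flipped back: `Elow = 2 Eup - env(2 Eup - S)`. Inside the
#' mask the ordering `Eup <= S <= Elow` (in z) holds up to smoothing
#' tolerance.
#'
#' @param s An [oct_surface()], hole-free inside the mask.
#' @param eup Its [upper_envelope()].
#' @param m An [oct_mask()].
#' @param cfg An [envelope_config()].
#' @param smooth Apply the final box filter.
#' @return The lower envelope as an [oct_surface()].
#' @export
lower_envelope <- function(s, eup, m, cfg = envelope_config(),
                           smooth = TRUE) {
  stopifnot(inherits(s, "oct_surface"), inherits(eup, "oct_surface"),
            inherits(m, "oct_mask"))
  if (!any(m$bits)) stop("empty mask", call. = FALSE)
  mirror <- 2 * eup$heights - s$heights
  e <- 2 * eup$heights - envelope_matrix(mirror, m$bits, cfg$l)
  if (smooth) {
    # re-clip after smoothing (see upper_envelope): S <= Elow, Eup <= Elow
    e <- pmax(masked_box_mean(e, m$bits, cfg$smooth_px), s$heights,
              eup$heights)
  }
  oct_surface(clamp(e, 0, s$nz - 1), nz = s$nz, pitch = s$pitch)
}
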