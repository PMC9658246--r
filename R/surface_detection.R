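# ---------------------------------------------------------------------------
# Coarse-to-fine surface segmentation over the volume pyramid with
# per-scan-line kernel-size selection, region narrowing, and hole collapse.
# ---------------------------------------------------------------------------

# internal: condition helpers. Format errors come from malformed inputs,
# processing errors from scans the chain cannot segment.
abort_format <- function(msg) {
  stop(structure(class = c("octseg_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
abort_processing <- function(msg) {
  stop(structure(class = c("octseg_processing_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Surface-detection configuration
#'
#' Tunable parameters of the coarse-to-fine segmentation. The values below
#' substitute the hardware-dependent constants of a deployed scanner setup
#' and are logged at the start of every [segment_fingerprint()] run so they
#' remain auditable.
#'
#' @param f_w Region scaling factor (> 1): the search-band half-width at each
#'   pyramid level is `f_w` times the weighted-median kernel size of the
#'   previous (coarser) detection run.
#' @param w_N Initial search region size in voxels at the coarsest level;
#'   `NULL` (default) means the full depth, since the finger position is
#'   initially unknown.
#' @param L_N Kernel sizes (even, full-resolution units); halved per
#'   downsampling level with a floor of 2.
#' @param r_var Neighborhood radius for the weighted standard deviation used
#'   to select the per-line kernel.
#' @param N Pyramid depth; `NULL` picks `log2(min dim) - 5` clamped to
#'   `[1, 4]` (3 for a 256-cube, 4 for a 1024-cube).
#' @param z_min Lower axial bound (full-resolution voxels) of every search
#'   band; used by the inner-fingerprint pass to exclude the truncation
#'   boundary left by flattening.
#' @param max_hole_iters Iteration cap for [fill_holes()].
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(f_w = 1.5, w_N = NULL, L_N = c(4, 6, 8, 12, 16),
                             r_var = 2, N = NULL, z_min = 0,
                             max_hole_iters = 1000) {
  if (f_w <= 1) stop("f_w must be > 1", call. = FALSE)
  if (any(L_N < 2) || any(L_N %% 2 != 0))
    stop("all kernel sizes must be even and >= 2", call. = FALSE)
  if (r_var < 1) stop("r_var must be >= 1", call. = FALSE)
  structure(list(f_w = f_w, w_N = w_N, L_N = sort(unique(as.integer(L_N))),
                 r_var = as.integer(r_var), N = N,
                 z_min = as.integer(z_min),
                 max_hole_iters = as.integer(max_hole_iters)),
            class = "detection_config")
}

#' Read a detection configuration from a YAML key-value file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [detection_config()].
#' @export
read_detection_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(detection_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    abort_format(paste("unknown detection config keys:",
                       paste(bad, collapse = ", ")))
  do.call(detection_config, vals)
}

# internal: default pyramid depth for a volume
default_pyramid_depth <- function(dims) {
  max(1L, min(4L, as.integer(floor(log2(min(dims)))) - 5L))
}

# internal: box sum over a (2r+1)^2 window, truncated at image borders
box_sum <- function(m, r) {
  nx <- nrow(m); ny <- ncol(m)
  cs <- apply(m, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  I <- matrix(0, nx + 1L, ny + 1L)
  I[2:(nx + 1L), 2:(ny + 1L)] <- cs
  x2 <- pmin(seq_len(nx) + r, nx) + 1L
  x1 <- pmax(seq_len(nx) - r, 1L)
  y2 <- pmin(seq_len(ny) + r, ny) + 1L
  y1 <- pmax(seq_len(ny) - r, 1L)
  I[x2, y2] - I[x1, y2] - I[x2, y1] + I[x1, y1]
}

# internal: box mean with border truncation (window renormalized to the
# in-image area)
box_mean <- function(m, r) {
  box_sum(m, r) / box_sum(matrix(1, nrow(m), ncol(m)), r)
}

#' Detect candidate surface positions for every scan line and kernel size
#'
#' Runs the normalized edge filter of every kernel size in `Ls` over each
#' A-scan, restricted to the axial search region, and records the peak
#' position (validity-gated, sub-voxel refined) and peak response (the
#' weight). Lines with no valid candidate for any kernel are holes.
#'
#' @param v An [oct_volume()].
#' @param region An [oct_region()] matching the lateral grid.
#' @param Ls Even kernel sizes.
#' @param mask Optional [oct_mask()]; unmasked lines are skipped and marked
#'   hole.
#' @return An object of class `result_set`: per kernel size, matrices `pos`
#'   (fractional z, `NA` = no valid candidate) and `wt` (peak response within
#'   the region, >= 0).
#' @export
detect_surface <- function(v, region, Ls, mask = NULL) {
  stopifnot(inherits(v, "oct_volume"), inherits(region, "oct_region"))
  Ls <- sort(unique(as.integer(Ls)))
  if (!length(Ls)) stop("empty kernel set", call. = FALSE)
  if (any(Ls < 2) || any(Ls %% 2 != 0))
    stop("kernel sizes must be even and >= 2", call. = FALSE)
  d <- dim(v$data)
  if (!all(dim(region$lo) == d[1:2]))
    stop("region grid does not match the volume", call. = FALSE)
  Ls <- Ls[Ls + 2 <= d[3]]
  if (!length(Ls))
    stop("volume too shallow for every kernel in the set", call. = FALSE)
  smat <- matrix(aperm(v$data, c(3L, 1L, 2L)), d[3], d[1] * d[2])
  mbits <- if (is.null(mask)) rep(TRUE, d[1] * d[2]) else as.vector(mask$bits)
  zlo <- as.integer(floor(as.vector(region$lo)))
  zhi <- as.integer(ceiling(as.vector(region$hi)))
  pos <- wt <- stats::setNames(vector("list", length(Ls)), as.character(Ls))
  for (i in seq_along(Ls)) {
    k <- normalize_kernels(make_kernels(Ls[i]))
    res <- detect_lines_cpp(smat, k$L, k$scale, zlo, zhi, mbits)
    pos[[i]] <- matrix(res$pos, d[1], d[2])
    wt[[i]] <- matrix(res$wt, d[1], d[2])
  }
  structure(list(Ls = Ls, pos = pos, wt = wt, dims = d[1:2], nz = d[3]),
            class = "result_set")
}

#' Select the best kernel per scan line and assemble the surface
#'
#' Skin-layer thickness varies across a fingertip, so no single kernel size
#' fits everywhere; but it varies slowly, so the kernel that agrees best with
#' its neighbors is the most reliable. For every lateral position and kernel,
#' the weighted standard deviation of that kernel's candidate positions over
#' the `(2 r_var + 1)^2` neighborhood is computed (weights = peak responses,
#' holes excluded); the kernel with the lowest deviation wins, ties going to
#' the smaller kernel. Positions where no kernel produced a valid candidate
#' remain holes, as do positions whose winning candidate contradicts its own
#' kernel's neighborhood consensus (deviation from the weighted neighborhood
#' mean beyond `max(3 sd, 2)` voxels): an isolated speckle edge that slips
#' through the validity gate is better interpolated from its neighbors than
#' kept, especially since the upper envelope must later touch every
#' topmost point of the surface.
#'
#' @param rs A [detect_surface()] result set.
#' @param r_var Neighborhood radius.
#' @return An [oct_surface()] with extra fields `kernel` (chosen size per
#'   position) and `weight` (its peak response), both `NA` at holes.
#' @export
select_kernel_per_line <- function(rs, r_var = 2) {
  stopifnot(inherits(rs, "result_set"))
  nx <- rs$dims[1]; ny <- rs$dims[2]
  best_sd <- matrix(Inf, nx, ny)
  h <- matrix(NA_real_, nx, ny)
  kn <- matrix(NA_integer_, nx, ny)
  kw <- matrix(NA_real_, nx, ny)
  dev <- matrix(0, nx, ny)
  for (i in seq_along(rs$Ls)) {
    p <- rs$pos[[i]]
    ok <- !is.na(p)
    if (!any(ok)) next
    w <- rs$wt[[i]]
    w[!ok] <- 0
    p0 <- p
    p0[!ok] <- 0
    sw <- box_sum(w, r_var)
    m1 <- box_sum(w * p0, r_var) / sw
    v1 <- box_sum(w * p0 * p0, r_var) / sw - m1 * m1
    sdev <- sqrt(pmax(v1, 0))
    sdev[sw <= 0 | !ok] <- Inf
    take <- ok & (sdev < best_sd)       # strict: ties keep the smaller L
    best_sd[take] <- sdev[take]
    h[take] <- p[take]
    kn[take] <- rs$Ls[i]
    kw[take] <- w[take]
    dev[take] <- abs(p[take] - m1[take])
  }
  # consensus gate: an isolated candidate far from its own kernel's local
  # weighted mean is an outlier; demote it to a hole for interpolation
  spike <- !is.na(h) & dev > pmax(3 * best_sd, 2)
  h[spike] <- NA_real_
  kn[spike] <- NA_integer_
  kw[spike] <- NA_real_
  s <- oct_surface(h, nz = rs$nz)
  s$kernel <- kn
  s$weight <- kw
  s
}

# internal: weighted median kernel size; smallest L whose cumulative weight
# reaches half the total (deterministic tie-break toward small kernels)
weighted_median_kernel <- function(kn, kw) {
  ok <- !is.na(kn)
  if (!any(ok)) abort_processing("no valid surface candidates in any line")
  tw <- tapply(kw[ok], kn[ok], sum)
  Ls <- as.integer(names(tw))
  o <- order(Ls)
  cum <- cumsum(tw[o])
  Ls[o][which(cum >= cum[length(cum)] / 2)[1]]
}

#' Narrow the axial search region around a detected surface
#'
#' Kernel size correlates with skin-layer thickness, so the trusted band
#' around the previous surface estimate is sized from the weighted median of
#' the kernels chosen in the previous detection run (weights = the maximum
#' filter response within the previous region): half-width
#' `f_w * median_L * scale`, where `scale` accounts for pyramid levels
#' ascended since that run. Bands are clipped to the volume; lateral
#' positions with no surface estimate (outside the mask) get the full depth.
#'
#' @param s Surface at the NEW level (upscaled and hole-filled inside the
#'   mask), heights in new-level voxel units.
#' @param sel The [select_kernel_per_line()] surface of the previous run
#'   (provides chosen kernels and weights).
#' @param f_w Region scaling factor.
#' @param scale Axial scale factor between the previous run and `s` (2 when
#'   ascending one pyramid level).
#' @return An [oct_region()] on the grid of `s`.
#' @export
narrow_region <- function(s, sel, f_w = 1.5, scale = 2) {
  stopifnot(inherits(s, "oct_surface"), inherits(sel, "oct_surface"))
  medL <- weighted_median_kernel(sel$kernel, sel$weight)
  hw <- f_w * medL * scale
  nz <- s$nz
  h <- s$heights
  lo <- floor(h - hw); hi <- ceiling(h + hw)
  lo[is.na(h)] <- 0; hi[is.na(h)] <- nz - 1
  lo <- clamp(lo, 0, nz - 1); hi <- clamp(hi, 0, nz - 1)
  r <- oct_region(lo, hi, nz)
  r$median_kernel <- medL
  r
}

# internal: 8-neighbor sums of values and of defined-ness
neigh_stats8 <- function(h, def) {
  nx <- nrow(h); ny <- ncol(h)
  hz <- h; hz[!def] <- 0
  hp <- matrix(0, nx + 2L, ny + 2L); hp[2:(nx + 1L), 2:(ny + 1L)] <- hz
  cp <- matrix(0, nx + 2L, ny + 2L); cp[2:(nx + 1L), 2:(ny + 1L)] <- def
  sx <- seq_len(nx); sy <- seq_len(ny)
  nsum <- matrix(0, nx, ny); ncnt <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    nsum <- nsum + hp[sx + 1L + dx, sy + 1L + dy]
    ncnt <- ncnt + cp[sx + 1L + dx, sy + 1L + dy]
  }
  list(sum = nsum, cnt = ncnt)
}

# internal: iterative hole collapse on a plain heights matrix
fill_matrix_holes <- function(h, inside = NULL, max_iters = 1000) {
  if (is.null(inside)) inside <- matrix(TRUE, nrow(h), ncol(h))
  def <- !is.na(h)
  if (!any(def & inside))
    abort_processing("surface has no defined heights inside the mask")
  it <- 0L
  while (any(inside & !def)) {
    it <- it + 1L
    if (it > max_iters)
      abort_processing("hole filling did not converge")
    ns <- neigh_stats8(h, def)
    upd <- inside & !def & ns$cnt > 0
    if (!any(upd)) abort_processing("isolated holes cannot be filled")
    h[upd] <- ns$sum[upd] / ns$cnt[upd]   # double-buffered: one sweep per pass
    def[upd] <- TRUE
  }
  h
}

#' Collapse surface holes by repeated perimeter interpolation
#'
#' Every hole adjacent to at least one defined neighbor is assigned the mean
#' of its defined 8-neighbors; passes repeat (double-buffered, so the sweep
#' order is immaterial) until no holes remain inside the mask. Positions
#' outside the mask are left untouched.
#'
#' @param s An [oct_surface()].
#' @param m Optional [oct_mask()] restricting where holes must be filled.
#' @param max_iters Iteration cap; non-convergence is a processing error.
#' @return The hole-free (inside the mask) `oct_surface`.
#' @export
fill_holes <- function(s, m = NULL, max_iters = 1000) {
  stopifnot(inherits(s, "oct_surface"))
  inside <- if (is.null(m)) NULL else m$bits
  s$heights <- fill_matrix_holes(s$heights, inside, max_iters)
  s
}

# internal: bilinear 2x upscale of a surface to the next-finer level.
# Heights are in voxel units of their level, so the axial value maps as
# h_fine = 2 h_coarse + 1/2 (center-aligned grids); NA propagates.
upscale_surface <- function(s, nz_fine) {
  h <- s$heights
  ix <- up2_index(nrow(h)); iy <- up2_index(ncol(h))
  m1 <- h[ix$lo, , drop = FALSE] * (1 - ix$w) +
        h[ix$hi, , drop = FALSE] * ix$w
  m2 <- m1[, iy$lo, drop = FALSE] * rep(1 - iy$w, each = nrow(m1)) +
        m1[, iy$hi, drop = FALSE] * rep(iy$w, each = nrow(m1))
  oct_surface(clamp(2 * m2 + 0.5, 0, nz_fine - 1), nz = nz_fine,
              pitch = s$pitch / 2)
}

# internal: 2x lateral mask reduction; a coarse cell is covered when ANY of
# its four children is (inclusive, so masked detection never starves)
downsample_mask <- function(m) {
  b <- m$bits
  i <- seq(1L, nrow(b), 2L); j <- seq(1L, ncol(b), 2L)
  oct_mask(b[i, j] | b[i + 1L, j] | b[i, j + 1L] | b[i + 1L, j + 1L])
}

#' Segment a fingerprint surface from a prepared volume
#'
#' The full coarse-to-fine chain: build the volume pyramid, contrast-enhance
#' it, then from the coarsest level to full resolution run
#' [detect_surface()] within the current search region,
#' [select_kernel_per_line()], [fill_holes()], upscale the surface and
#' [narrow_region()] for the next level. Kernel sizes are halved per
#' downsampling level (floor 2, kept even); the initial region spans the
#' whole depth because the finger position is unknown.
#'
#' The input volume is expected to be cast to uint8 and roll-off compensated
#' (see [cast_to_uint8()], [rolloff_compensate()]).
#'
#' @param v An [oct_volume()].
#' @param cfg A [detection_config()].
#' @param m Optional [oct_mask()]: only masked lines are segmented (used for
#'   the inner-fingerprint pass).
#' @return The full-resolution [oct_surface()] (hole-free inside the mask),
#'   with a `log` field recording configuration and per-level diagnostics.
#' @export
segment_fingerprint <- function(v, cfg = detection_config(), m = NULL) {
  stopifnot(inherits(v, "oct_volume"))
  d <- dim(v$data)
  if (any(d < 8)) stop("degenerate volume", call. = FALSE)
  N <- if (is.null(cfg$N)) default_pyramid_depth(d) else as.integer(cfg$N)
  if (any(d %% 2^N != 0))
    abort_format(sprintf("volume dims %s not divisible by 2^%d",
                         paste(d, collapse = "x"), N))
  p <- contrast_enhance(build_pyramid(v, N))
  masks <- vector("list", N + 1L)
  if (!is.null(m)) {
    masks[[1L]] <- m
    for (n in seq_len(N)) masks[[n + 1L]] <- downsample_mask(masks[[n]])
  }
  log <- list(config = unclass(cfg), N = N, levels = list())
  level_Ls <- function(n) {
    Ls <- cfg$L_N %/% 2L^n
    Ls <- 2L * (Ls %/% 2L)              # keep even
    sort(unique(pmax(2L, Ls)))
  }
  region <- NULL
  sel <- NULL
  for (n in seq(N, 0L)) {
    vn <- p$levels[[n + 1L]]
    dn <- dim(vn$data)
    zmin_n <- min(as.integer(ceiling(cfg$z_min / 2^n)), dn[3] - 1L)
    if (is.null(region)) {
      zmax_n <- dn[3] - 1L
      if (!is.null(cfg$w_N))
        zmax_n <- min(zmax_n, zmin_n + as.integer(cfg$w_N) - 1L)
      region <- full_region(dn[1], dn[2], dn[3], z_min = zmin_n)
      region$hi[] <- zmax_n
    }
    Ls <- level_Ls(n)
    rs <- detect_surface(vn, region, Ls, masks[[n + 1L]])
    sel_new <- select_kernel_per_line(rs, cfg$r_var)
    n_holes <- sum(is.na(sel_new$heights) &
                   (if (is.null(masks[[n + 1L]])) TRUE
                    else masks[[n + 1L]]$bits))
    sel_new <- tryCatch(
      fill_holes(sel_new, masks[[n + 1L]], cfg$max_hole_iters),
      octseg_processing_error = function(e)
        abort_processing(sprintf("no surface found at pyramid level %d: %s",
                                 n, conditionMessage(e))))
    log$levels[[as.character(n)]] <-
      list(dims = dn, kernels = Ls, holes_filled = n_holes,
           region_halfwidth = if (!is.null(region$median_kernel))
             cfg$f_w * region$median_kernel * 2 else NA)
    if (n > 0L) {
      s_up <- upscale_surface(sel_new, nz_fine = dim(p$levels[[n]]$data)[3])
      region <- narrow_region(s_up, sel_new, cfg$f_w, scale = 2)
      zmin_next <- min(as.integer(ceiling(cfg$z_min / 2^(n - 1L))),
                       dim(p$levels[[n]]$data)[3] - 1L)
      region$lo <- pmax(region$lo, zmin_next)
      region$hi <- pmax(region$hi, region$lo)
    }
    sel <- sel_new
  }
  sel$pitch <- v$pitch
  sel$log <- log
  sel
}
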