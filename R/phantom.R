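# ---------------------------------------------------------------------------
# Synthetic OCT fingertip phantom with exact ground truth. Real OCT
# fingertip data are subject to data-protection constraints, so the phantom
# emulates the features the chain exploits: a curved fingertip suspended in
# air, a bright thin air-skin boundary carrying a ridge pattern, a dimmer
# junction layer carrying the same pattern, multiplicative speckle, and a
# linear depth-dependent intensity roll-off.
# ---------------------------------------------------------------------------

#' Phantom specification
#'
#' All geometry is in voxels of the phantom grid; the default pitch
#' (20 x 20 x 5.5 um) makes the defaults anatomically plausible: a 24 px
#' ridge period is ~480 um, a ridge depth of 8 axial voxels is ~44 um of
#' ridge relief, and an epidermis depth of 50 axial voxels puts the junction
#' ~275 um below the surface.
#'
#' @param dims Volume dimensions `(Nx, Ny, Nz)`.
#' @param pitch Voxel pitch in micrometres.
#' @param curvature_radius Fingertip curvature radius in lateral voxels
#'   (`Inf` = flat slab); the surface is a paraboloid cap sagging away from
#'   the scan top.
#' @param apex_depth Depth (axial voxels) of the fingertip apex below the
#'   scan top.
#' @param ridge_period Lateral ridge period T (voxels).
#' @param ridge_depth Peak-to-valley ridge relief A (axial voxels); ridge
#'   tops protrude toward the scan top. Must be `< epidermis_depth`.
#' @param ridge_theta Ridge-normal orientation (radians).
#' @param epidermis_depth Depth D of the dermal-epidermal junction below the
#'   outer surface (axial voxels).
#' @param junction_ridge_depth Ridge relief of the junction layer (the
#'   junction carries the same ridge pattern, as the template of the outer
#'   fingerprint).
#' @param contact_radius Fingertip silhouette radius in lateral voxels
#'   (ground-truth mask); `Inf` = full coverage.
#' @param center Lateral offset `(dx, dy)` of the fingertip center (voxels).
#' @param tilt Axial tilt `(per-x, per-y)`: voxels of extra depth per
#'   lateral voxel.
#' @param scar `NULL`, or `list(width, depth)`: a straight groove of the
#'   given lateral width (voxels) and extra depth (axial voxels) pressed
#'   into the OUTER surface only, running along the ridge normal so it
#'   crosses the ridges; the junction layer is unaffected, emulating
#'   superficial skin damage.
#' @param brightness Named intensities: `surface`, `junction`, `tissue`,
#'   `background`; must be strictly decreasing in that order.
#' @param band_sigma Gaussian cross-section (axial voxels) of the boundary
#'   layers on their deep (tissue) side (~2-voxel bright band). The shallow
#'   (air) side falls off three times faster: an interface reflection
#'   arises at and below the boundary, not in the air above it, so the
#'   bright band has a sharp upper flank softened only by the axial
#'   point-spread function.
#' @param speckle_sigma Multiplicative speckle contrast
#'   (`I * max(0, 1 + sigma * N(0,1))`).
#' @param rolloff_slope Linear intensity roll-off per voxel of depth
#'   (`I * (1 - a z)`).
#' @param attenuation Exponential attenuation per voxel of depth below the
#'   surface.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(256, 256, 256),
                         pitch = c(20, 20, 5.5),
                         curvature_radius = 400,
                         apex_depth = 30,
                         ridge_period = 24,
                         ridge_depth = 8,
                         ridge_theta = pi / 6,
                         epidermis_depth = 50,
                         junction_ridge_depth = 6,
                         contact_radius = 110,
                         center = c(0, 0),
                         tilt = c(0, 0),
                         scar = NULL,
                         brightness = c(surface = 230, junction = 140,
                                        tissue = 60, background = 8),
                         band_sigma = 1.2,
                         speckle_sigma = 0.35,
                         rolloff_slope = 8e-4,
                         attenuation = 0.015,
                         seed = 42) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  b <- spec$brightness
  if (!all(c("surface", "junction", "tissue", "background") %in% names(b)))
    stop("brightness must name surface, junction, tissue, background",
         call. = FALSE)
  if (!(b["surface"] > b["junction"] && b["junction"] > b["tissue"] &&
        b["tissue"] > b["background"]))
    stop("brightness ordering surface > junction > tissue > background",
         call. = FALSE)
  if (spec$ridge_depth >= spec$epidermis_depth)
    stop("ridge_depth must be < epidermis_depth", call. = FALSE)
  if (spec$epidermis_depth -
      (spec$ridge_depth - spec$junction_ridge_depth) <= 0)
    stop("junction must lie strictly below the outer surface", call. = FALSE)
  if (any(spec$dims < 8)) stop("dims must be >= 8", call. = FALSE)
  invisible(spec)
}

# internal: run expr with a private, restored RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a phantom volume with ground truth
#'
#' Construction: the outer surface is a paraboloid cap
#' `S*(x, y) = apex + sag(rho) + tilt + A r(x, y)` with the ridge pattern
#' `r = (1 - cos(2 pi (x cos theta + y sin theta) / T)) / 2` (tops at
#' `r = 0`, i.e. closest to the scan top); the junction is
#' `I* = apex + sag + tilt + D + A_in r` — the same pattern with its own
#' relief, strictly below the surface. Voxel intensity is background outside
#' the fingertip silhouette; inside, a bright asymmetric-Gaussian band at
#' `S*` (sharp air-side flank, slower decay into the tissue), a dimmer
#' band at `I*` (attenuated by its depth below the surface), and tissue with
#' exponential decay in between and below. Multiplicative clipped-Gaussian
#' speckle and a linear roll-off are applied, then the volume is cast to
#' uint8.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (uint8 [oct_volume()]) and `truth` (class
#'   `phantom_truth`: surfaces `outer`, `inner`, mask `contact`, and
#'   `scar_area` when a scar is present; truth surfaces are `NA` outside the
#'   fingertip silhouette).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  xs <- seq_len(nx) - (nx + 1) / 2 - spec$center[1]
  ys <- seq_len(ny) - (ny + 1) / 2 - spec$center[2]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  # sag of the paraboloid cap, in axial voxels (pitch-aware)
  sag <- if (is.finite(spec$curvature_radius)) {
    rho2_um <- (X * spec$pitch[1])^2 + (Y * spec$pitch[2])^2
    rho2_um / (2 * spec$curvature_radius * spec$pitch[1]) / spec$pitch[3]
  } else matrix(0, nx, ny)
  u <- X * cos(spec$ridge_theta) + Y * sin(spec$ridge_theta)
  r <- (1 - cos(2 * pi * u / spec$ridge_period)) / 2
  base <- spec$apex_depth + sag + spec$tilt[1] * X + spec$tilt[2] * Y
  S <- base + spec$ridge_depth * r
  I <- base + spec$epidermis_depth + spec$junction_ridge_depth * r
  scar_area <- matrix(FALSE, nx, ny)
  if (!is.null(spec$scar)) {
    # groove along the ridge normal: crosses every ridge it meets
    vperp <- -X * sin(spec$ridge_theta) + Y * cos(spec$ridge_theta)
    scar_area <- abs(vperp) < spec$scar$width / 2
    prof <- cos(pi * vperp / spec$scar$width)^2
    S <- S + ifelse(scar_area, spec$scar$depth * prof, 0)
  }
  finger <- if (is.finite(spec$contact_radius))
    X^2 + Y^2 <= spec$contact_radius^2 else matrix(TRUE, nx, ny)
  if (any(c(S[finger], I[finger]) > nz - 4) || any(S[finger] < 1))
    stop("phantom geometry does not fit the volume depth", call. = FALSE)
  b <- spec$brightness
  junc_gain <- exp(-spec$attenuation * (I - S))
  vol <- array(0, dim = d)
  sig2_deep <- 2 * spec$band_sigma^2
  sig2_air <- 2 * (spec$band_sigma / 3)^2
  band <- function(dz) exp(-dz^2 / ifelse(dz < 0, sig2_air, sig2_deep))
  with_local_seed(spec$seed, {
    for (zi in seq_len(nz)) {
      z <- zi - 1
      tz <- z - S                         # depth below the outer surface
      sl <- matrix(b["background"], nx, ny)
      tissue <- finger & tz > 0
      sl[tissue] <- sl[tissue] + b["tissue"] *
        exp(-spec$attenuation * tz[tissue])
      sl[finger] <- sl[finger] + b["surface"] * band(tz[finger]) +
        (b["junction"] * junc_gain[finger]) * band(z - I[finger])
      if (spec$speckle_sigma > 0)
        sl <- sl * pmax(0, 1 + spec$speckle_sigma * matrix(rnorm(nx * ny),
                                                           nx, ny))
      vol[, , zi] <- sl * (1 - spec$rolloff_slope * z)
    }
  })
  volume <- cast_to_uint8(oct_volume(vol, pitch = spec$pitch,
                                     dtype = "float32"))
  Sna <- S; Sna[!finger] <- NA_real_
  Ina <- I; Ina[!finger] <- NA_real_
  truth <- structure(
    list(outer = oct_surface(clamp_na(Sna, 0, nz - 1), nz, spec$pitch),
         inner = oct_surface(clamp_na(Ina, 0, nz - 1), nz, spec$pitch),
         contact = oct_mask(finger),
         scar_area = scar_area),
    class = "phantom_truth")
  list(volume = volume, truth = truth)
}

# internal: clamp that passes NA through
clamp_na <- function(x, lo, hi) {
  ok <- !is.na(x)
  x[ok] <- clamp(x[ok], lo, hi)
  x
}

#' Named phantom presets
#'
#' * `flat-slab`: 64-cube, flat noiseless slab with full coverage — the
#'   analytic case for detection unit tests.
#' * `clean-finger-256`: the reference curved, ridged, speckled fingertip.
#' * `noisy-finger-256`: stronger speckle and roll-off.
#' * `scarred-finger`: `clean-finger-256` plus a superficial groove crossing
#'   the ridges; the junction layer is identical to the clean preset, so the
#'   inner fingerprint should be unaffected.
#' * `off-center-tilted`: displaced, tilted fingertip for masking
#'   robustness.
#'
#' @param name Preset name; omit for the list of all presets.
#' @param seed Optional seed override.
#' @return A [phantom_spec()], or a named list of them.
#' @export
phantom_preset <- function(name, seed = NULL) {
  specs <- list(
    "flat-slab" = phantom_spec(dims = c(64, 64, 64), curvature_radius = Inf,
                               apex_depth = 20, ridge_depth = 0,
                               junction_ridge_depth = 0,
                               epidermis_depth = 24,
                               contact_radius = Inf, speckle_sigma = 0,
                               rolloff_slope = 0),
    "clean-finger-256" = phantom_spec(),
    "noisy-finger-256" = phantom_spec(speckle_sigma = 0.55,
                                      rolloff_slope = 1.2e-3),
    "scarred-finger" = phantom_spec(scar = list(width = 10, depth = 6)),
    "off-center-tilted" = phantom_spec(center = c(30, -20),
                                       tilt = c(0.06, -0.04),
                                       contact_radius = 95))
  if (missing(name)) return(specs)
  if (!name %in% names(specs))
    stop(sprintf("unknown preset '%s' (have: %s)", name,
                 paste(names(specs), collapse = ", ")), call. = FALSE)
  spec <- specs[[name]]
  if (!is.null(seed)) spec$seed <- seed
  spec
}

#' @rdname phantom_preset
#' @export
phantom_presets <- function() phantom_preset()

#' RMSE between a detected surface and a ground-truth surface
#'
#' @param s Detected [oct_surface()].
#' @param truth Ground-truth [oct_surface()].
#' @param m Optional [oct_mask()] restricting the comparison.
#' @return Root-mean-square height error in axial voxels, over positions
#'   where both surfaces are defined (inside the mask).
#' @export
surface_rmse <- function(s, truth, m = NULL) {
  stopifnot(inherits(s, "oct_surface"), inherits(truth, "oct_surface"))
  ok <- !is.na(s$heights) & !is.na(truth$heights)
  if (!is.null(m)) ok <- ok & m$bits
  if (!any(ok)) stop("no overlapping defined positions", call. = FALSE)
  sqrt(mean((s$heights[ok] - truth$heights[ok])^2))
}
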