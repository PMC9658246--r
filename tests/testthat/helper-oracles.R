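# Independent oracles used across tests. These deliberately avoid the code
# paths they check: dense convolution goes through stats::convolve (FFT),
# weighted statistics are computed by direct loops.

# Full zero-padded convolution with the normalized dense edge kernel,
# trimmed to the same alignment the package uses (out[z] = full[z + L/2 - 1],
# 1-based).
dense_edge_response <- function(line, L) {
  h <- L / 2
  k0 <- c(seq_len(h), -rev(seq_len(h))) * (2 / L) / (L / 2 + 1)
  full <- stats::convolve(line, rev(k0), type = "open")
  full[(h):(h + length(line) - 1)]
}

# Zero-padded first difference: d[i] = x[i] - x[i-1] with x[0]=x[n+1]=0
pad_diff <- function(x) diff(c(0, x, 0))

# Direct weighted standard deviation (population form, frequency weights)
weighted_sd <- function(p, w) {
  sw <- sum(w)
  m <- sum(w * p) / sw
  sqrt(sum(w * (p - m)^2) / sw)
}

# A small flat-slab phantom for detection tests
flat_slab_spec <- function(dims = c(64, 64, 64), depth = 20, ...) {
  args <- list(dims = dims, curvature_radius = Inf, apex_depth = depth,
               ridge_depth = 0, junction_ridge_depth = 0,
               epidermis_depth = 16, contact_radius = Inf,
               speckle_sigma = 0, rolloff_slope = 0)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# A mid-size curved, ridged, speckled phantom that exercises the full chain
# quickly (quarter the voxel count of the reference preset)
small_finger_spec <- function(seed = 42, ...) {
  phantom_spec(dims = c(128, 128, 128), contact_radius = 55,
               apex_depth = 24, epidermis_depth = 40, curvature_radius = 300,
               seed = seed, ...)
}
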