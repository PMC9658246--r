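---
title: "Locating outer and inner fingerprints in OCT volumes: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating outer and inner fingerprints in OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octseg)
```

This vignette explains the science and the engineering behind `octseg`: the
models each stage assumes, the tunable parameters and why their defaults
are what they are, what the synthetic phantom does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## 1. The setting

A volumetric OCT fingertip scan is a grid of intensity voxels, nominally
1024×1024×1024 at ~20 µm lateral and ~5.5 µm axial pitch. The finger is
suspended in air above the scan head (no contact plate, so the skin is
undeformed), aligned so that the skin surface sits near the top edge of the
volume. Throughout the package **z = 0 is the top of the scan** and z grows
with depth; "highest ridge" therefore always means *smallest z*. Two
boundaries matter:

* the **air–skin boundary** (the outer fingerprint): a strong specular
  reflection, the brightest feature of the scan;
* the **dermal–epidermal junction** (the inner fingerprint): a dimmer
  scattering transition roughly 0.2–0.5 mm below the surface, carrying the
  same ridge pattern.

Two properties of OCT shape everything downstream: multiplicative speckle
noise, and a depth-dependent sensitivity loss ("roll-off") that makes the
curved fingertip's periphery dimmer than its apex.

## 2. The edge filter

Surfaces are located per A-scan with a 1D edge detector with low-pass
characteristics. The dense kernel of even size $L$ is

$$\kappa_L^{(0)} = [1, 2, \ldots, L/2,\; -L/2, \ldots, -2, -1].$$

Its zero-padded first difference is $\kappa_L^{(1)} = [1,\ldots,1,-L,1,\ldots,1]$,
and differencing again gives the sparse kernel

$$\kappa_L^{(2)} = [1, 0, \ldots, 0, -(L{+}1), (L{+}1), 0, \ldots, 0, -1],$$

with exactly four non-zero taps for every $L$. (The signs here are forced
by the difference construction: all three kernels must sum to zero, and
double cumulative summation of the $\kappa^{(2)}$ response must reproduce
the $\kappa^{(0)}$ response — `make_kernels()` asserts both.) Convolution
with the dense kernel is therefore computed as: 4-tap convolution, two
cumulative sums, plus the affine correction of the two integration
constants when the integration starts mid-line. Cost is $O(N_z)$
independent of $L$, which matters because good kernel sizes reach a
significant fraction of the scan-line length.

Normalization by $(2/L)/(L/2+1)$ makes the unit-step peak response exactly
$1/2$ for every even $L$, so responses of different kernel sizes can be
ranked against each other.

Numerical conventions, all covered by tests:

* **Boundary handling is zero padding**, consistent with the difference
  derivation of the sparse kernel.
* **Alignment**: the response is trimmed so that an ideal step at index
  $j$ peaks exactly at $j$, where the discrete response is symmetric; the
  sub-voxel parabolic refinement through the three samples around the peak
  is then unbiased on clean edges.
* **Validity gate**: a peak is accepted only if the response declines to
  zero within $L$ samples on *both* sides — a mismatched kernel smears the
  edge and fails this. "Zero" carries a $10^{-6}$ relative tolerance so
  float inputs whose background is not exactly constant behave like their
  quantized counterparts; running off the end of the line without a
  non-positive sample fails the gate, which also rejects the spurious peak
  at the truncation boundary of flattened volumes.
* **Odd kernel sizes are rejected**, not rounded: the kernel family is
  only defined for even $L$.
* Integer input is handled in doubles; the largest possible accumulator
  value ($N_z \cdot 255 \cdot (L{+}1)$) is far below the 2^53 integer
  precision of a double.

## 3. Preprocessing

**8-bit cast.** Scanner output is float32, but its value range covers the
dynamic range of the scan, so `cast_to_uint8()` clamps to [0, 255] and
truncates the decimals. On disk this quarters the footprint; in memory R
arrays stay doubles (R has no native uint8 arithmetic), so the tag records
the semantics rather than the storage width.

**Roll-off compensation.** The mean intensity of each en-face slice,
$A(z)$, is fit by ordinary least squares; the deviation of the fitted line
from the overall mean is subtracted per depth. The regression uses all
depths with no robust variant, and only means are corrected (no variance
rescaling). For uint8 volumes the per-depth correction is quantized to
whole intensity steps, so compensation never re-quantizes individual
voxels.

**Volume pyramid.** Downsampling is 2× per level *in all three
dimensions* (center-aligned trilinear reduction, which is exactly the
2×2×2 block mean). Keeping the aspect ratio avoids deforming the finger.
The default depth is $\log_2(\min \mathrm{dim}) - 5$ clamped to [1, 4] —
three levels for a 256-cube, four for a 1024-cube — so the coarsest level
retains ~32 voxels of depth, enough for the smallest kernel to operate.

**Contrast enhancement.** Up to a point, downsampled voxels represent the
fingerprint's macrostructure more reliably than their full-resolution
counterparts. Each coarse level is trilinearly upsampled — sampling at
positions offset from the coarse voxel centers, because naive doubling
creates cluster/edge artifacts (a constant coarse field must upsample to an
exactly constant fine field; tested) — and multiplied voxel-wise into its
finer neighbor. The product must be normalized back to the intensity
range. *This was a genuinely open design point.* An affine min–max rescale
of the product was tried first and rejected: its two rescaling constants
depend on the entire volume, so a local change to the scan (for example a
scratch) perturbs every enhanced voxel — and, through uint8 rounding, the
detected surface everywhere. The implemented normalization is the
**geometric mean**, $\sqrt{V_{i-1} \cdot U}$: content-independent,
monotone, overflow-free, and local. Voxels whose coarse and fine values
agree keep their value; voxels that disagree are pulled toward the dimmer
of the two.

## 4. Surface detection

Skin-layer thickness varies between fingers and within one fingertip, so
no single kernel size is right everywhere. Detection therefore runs a
*set* of kernel sizes per scan line (defaults {4, 6, 8, 12, 16} at full
resolution, halved per pyramid level with a floor of 2) and picks, per
line, the kernel whose candidate positions have the lowest weighted
standard deviation over a (2·2+1)² neighborhood, weights being the peak
filter responses. This rests on two assumptions: layer thickness changes
slowly across the fingertip, and curvature is negligible within the small
neighborhood. Ties go to the smaller kernel, deterministically.

Two safeguards handle failure modes:

* Lines where no kernel produces a gate-valid candidate become **holes**,
  collapsed afterwards by repeated 8-neighbor mean interpolation at the
  hole perimeter (double-buffered sweeps, so order is immaterial).
* A winning candidate that deviates from its own kernel's neighborhood
  weighted mean by more than $\max(3\sigma, 2)$ voxels is demoted to a
  hole too. This **consensus gate** is an addition of this implementation:
  without it ~1–2% of junction lines were isolated speckle spikes, almost
  all displaced *toward the scan top* — precisely the points the upper
  envelope is later obliged to touch, so each spike grew into a visible
  tent artifact.

The search region starts as the whole depth (the finger position is
unknown) and narrows while ascending the pyramid: it is re-centered on the
upscaled previous surface with half-width $f_w \times$ (weighted median of
the previously chosen kernel sizes) $\times 2$, the weighted median taken
with peak responses as weights and ties resolved toward smaller kernels.
The kernel size is a proxy for layer thickness, so the band is wide enough
to correct outliers but does not reach the adjacent layer. The scaling
factor $f_w = 1.5$ and the other constants in `detection_config()` stand in
for scanner-specific calibration; every value is recorded in the run log so
a deployment can audit them.

## 5. Masking

The segmented surface covers the whole scan area; the fingertip covers only
part of it. Shape priors (ellipse fitting and the like) fail on unusual
fingers, so the mask is derived from intensities alone: below the air–skin
boundary the maximum voxel value within a $w_n$-voxel band far exceeds the
maximum in the band above (air); outside the fingertip both bands sample
noise and the comparison is near a coin flip. A box blur sized to the
expected ridge distance (`ridge_px`, default 25 px ≈ one 500 µm ridge
period at 20 µm pitch) averages the coin flips toward one half while the
fingertip interior stays near one; Otsu's threshold re-binarizes; 4-connected
flood fill from the border identifies the exterior, interior islands are
filled and exterior islands cleared; one final blur + re-binarize pass
smooths the contour. The result is a single 4-connected component with no
holes (asserted by tests). 4-connectivity is deliberate: it prevents thin
diagonal leaks from merging regions. `w_n` defaults to 20 voxels, the
expected outer-layer thickness at full resolution.

## 6. Ridge envelopes

Flattening the volume against the ridged surface itself would transfer the
outer ridge pattern into the deeper layers (a "hybrid fingerprint"), so
flattening uses an **envelope**: a smooth heightmap that carries the finger
shape but, ideally, no ridge information. The API enforces this
structurally — `flatten_volume()` accepts only the envelope as reference,
never the raw surface.

The upper envelope is built per B-scan by a horizon search: starting at the
highest ridge (global minimum z), march outward; the next ridge top is the
candidate within the visibility window $l$ (default 2 × `ridge_px` = 50 px,
the expected maximum ridge spacing) that maximizes the elevation angle
toward the scan top. Two refinements of the "observable on the horizon"
idea proved necessary, and both are isolated inside `envelope_1d()` so the
operation can be swapped:

* **Candidates are restricted to local height minima** (ridge tops).
  Without this the march is a bounded convex-hull step, and on a surface
  whose overall slope is comparable to the ridge-flank slope (the
  periphery of every curved fingertip) the hull legitimately includes
  flank samples — the envelope then crawls down its own ridge flank and
  retains most of the ridge-band power it exists to discard (measured:
  ~70% retained as a hull, ~1% with the top restriction).
* **Sharp single-sample "V" minima (> 2 voxels below both neighbors) are
  not credible ridge tops** at 20 µm pitch — papillary ridges are tens of
  pixels wide — and are excluded, so isolated detection spikes cannot pin
  long tent artifacts into the envelope.

Between consecutive tops the envelope interpolates linearly and is finally
clipped to the profile, so `env ≤ profile` holds everywhere despite the
restriction to top candidates. A single pass dips into valleys where
ridges are crossed at a shallow angle, so the search runs along both
B-scan directions and the combination takes, per pixel, the value closest
to the scan top; the combination is symmetric (a transposition test
asserts it). A box filter (default `ridge_px`) removes residual roughness;
because averaging a curved envelope biases it past the ridge tops (the
mean of a convex depth profile exceeds its center value), the smoothed
envelope is re-clipped against the surface, which restores the defining
bound exactly — `min(S - E_up) = 0` holds to machine precision on the
phantom runs.

The lower envelope reuses the same machinery on the surface mirrored at
the upper envelope ($2E_{up} - S$ swaps peaks and valleys), flipped back
and clipped from below.

Idempotence is exact for profiles with equal-height ridge tops (tested on
interior samples); on curved profiles a second application can still
tighten the envelope slightly near clipped flank patches — re-application
is monotone (never moves away from the scan top), which is the property
the tests assert in general.

## 7. Flattening and the 3D-to-2D conversion

Each scan line is shifted toward the top by $E_S(x,y) + \Delta S$ with
$\Delta S = \max_{\text{mask}}(S - E_S)$, the height of the outer
fingerprint layer; everything at or above the outer surface leaves the
volume, so the second segmentation pass cannot re-detect it. Design
details:

* Shifts are **whole voxels** (no axial resampling); the per-line part is
  the rounded envelope and the global part the rounded-up $\Delta S$.
* The global part is additionally **rounded up to a multiple of the
  pyramid block size 2^N** (`snap`). Surface detection is exactly
  equivariant under a per-line integer shift at full resolution, but the
  pyramid's 2× blocks are not; snapping keeps the flattened grid aligned
  with the pyramid decomposition, which makes the inner-fingerprint result
  insensitive to small changes in the estimated outer-layer thickness
  (e.g. when a scratch deepens $\max(S - E_S)$). The cost is up to
  $2^N - 1$ voxels of extra truncation, negligible against the junction
  depth at the default scales.
* Outside the mask the envelope is extrapolated by outward 8-neighbor mean
  propagation (deterministic), and those lines are flagged in the record.
* The inner pass excludes a small top margin (`inner_z_margin`, 16
  full-resolution voxels, scaled per level) from its search region so the
  truncation boundary at the volume top is never mistaken for a layer
  edge; the gate's refusal to accept peaks whose response cannot decline
  on both sides provides a second line of defense.

The inner surface is unflattened by adding back the recorded shifts — the
exact inverse. Both fingerprints are then projected:
$\mathrm{FP2D} = \mathrm{clamp}\!\left((S - E_{up})/(E_{low} - E_{up}),\,0,\,1\right)$,
so ridge tops are dark (0), valley bottoms light (1), local envelope
separation normalizes natural ridge-height variation, degenerate pixels
(separation below $10^{-6}$ voxel) become featureless 0.5, and everything
outside the mask is background white. The single mask from the outer pass
is reused for the inner output. Output resolution is the native lateral
grid (~1270 ppi at 20 µm pitch) with optional resampling to the 500 ppi
expected by standard minutiae extractors.

## 8. The phantom: what it emulates, and what it does not

Real scans of real fingers are personal data; the study conditions are
therefore reproduced by a parametric phantom with exact ground truth:

* a paraboloid fingertip cap (default curvature radius 400 lateral voxels
  = 8 mm) with apex 30 voxels below the scan top;
* a cosine ridge pattern, period 24 px (480 µm) at orientation 30°, with
  peak-to-valley relief 8 axial voxels (44 µm) on the outer surface and 6
  on the junction, same phase (the junction is the template of the outer
  print);
* junction depth 50 axial voxels (275 µm) below the surface;
* brightness ordering surface (230) > junction (140) > tissue (60) >
  background (8), the surface and junction as thin bands with a sharp
  flank toward the shallow side — an interface reflection arises at and
  below the boundary, not in the air above it — and exponential
  attenuation ($\mu = 0.015$/voxel) below the surface;
* multiplicative clipped-Gaussian speckle (contrast 0.35; the noisy preset
  uses 0.55) and a linear roll-off of $8 \times 10^{-4}$ per voxel of
  depth (~20% over the volume);
* presets for the reference fingertip, a noisy variant, a displaced tilted
  variant, a flat noiseless slab, and a scarred variant whose only change
  is a 10 px wide, 6 voxel deep groove pressed into the *outer* surface
  across the ridges — the junction is bit-identical to the clean preset,
  which makes the central claim (the inner fingerprint is unaffected by
  superficial damage) literally testable.

Default test scale is a 256-cube; the generator handles the native
1024-cube but the tests do not require it. The phantom does **not** model:
the double-rowed microstructure of the junction, sweat ducts, coherent
(correlated) speckle, presentation-attack artifacts, or real anatomical
ridge-pattern statistics (loops, whorls, minutiae). Passing tests
therefore demonstrate the signal-processing chain's correctness under
realistic geometry, contrast, noise and roll-off — not matcher-level
biometric performance, which requires real fingers and a minutiae
extractor.

## 9. Problem sizes and determinism

The test suite runs the full chain on 128- and 256-cube phantoms — sizes
chosen so a desk machine exercises every stage, including two full
pipeline runs for the scar comparison, in minutes; `scripts/acceptance.R`
re-runs the presets at the 256-cube reference scale. Every stage is
deterministic: the only randomness anywhere is the phantom's seeded
speckle, generation restores the caller's RNG state, and re-running the
pipeline on the same volume reproduces bit-identical outputs (tested).

## 10. Known limitations

* The per-kernel detection position has a small systematic offset (a few
  tenths of a voxel, kernel-size dependent) between the peak filter
  response and the physical band center; at the default scales this is
  well inside the acceptance tolerances but it would matter for
  sub-micrometre metrology.
* The envelope's horizon search is a reconstruction with two documented
  refinements (top candidacy, sharp-V exclusion); other readings of
  "observable on the horizon" are possible and the operation is isolated
  so they can be swapped in.
* Masking assumes the fingertip does not touch the scan-area border
  everywhere (the exterior flood fill needs border background) and errors
  out on full-coverage scans rather than guessing.
* Flattening is integer-voxel; sub-voxel axial resampling is out of scope.
* Performance targets real-time GPU deployment in the original setting;
  this implementation favors clarity and testability (R with one small
  C++ kernel) and processes a 256-cube in tens of seconds, not a 1024-cube
  in under a second.
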