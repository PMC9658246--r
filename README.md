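# octseg

Segmentation of outer and inner fingerprints from volumetric optical
coherence tomography (OCT) fingertip scans.

An OCT scanner captures a fingertip as a 3D intensity volume: a stack of
depth profiles (A-scans) in which the air–skin boundary appears as a bright
thin layer and the dermal–epidermal junction as a dimmer band a few hundred
micrometres below it. Both layers carry the same friction-ridge pattern —
the junction is the living template from which the epidermal surface is
continuously renewed — so a single contactless scan yields two fingerprints:
the conventional **outer** fingerprint on the skin surface, and an **inner**
fingerprint that is unaffected by superficial damage such as scratches,
abrasion, or adhering dirt. `octseg` implements the complete digital
signal-processing chain that locates both surfaces in a scan volume and
converts them to conventional 2D grayscale fingerprint images, for
researchers working on contactless fingerprint capture and presentation
attack detection.

## The method

Surfaces are found per A-scan with an adaptive 1D edge filter. The dense
kernel of even size $L$,

$$\kappa_L^{(0)} = [\,1, 2, \ldots, \tfrac{L}{2}, -\tfrac{L}{2}, \ldots, -2, -1\,],$$

is differentiated twice (with zero padding) into a sparse kernel with
exactly four non-zero taps $\{+1, -(L{+}1), +(L{+}1), -1\}$; convolving with
the sparse kernel and integrating (cumulatively summing) twice reproduces
the dense response in a single pass whose cost is independent of $L$.
Kernels are normalized by $(2/L)/(L/2+1)$ so that the peak response on a
unit step is $1/2$ for every size, making responses comparable across
kernels.

Around the filter sit the stages of the chain:

1. **Cast to uint8** — the scanner's float32 range is integer-valued, so
   8-bit processing loses only decimal places.
2. **Intensity roll-off compensation** — a linear regression of the
   per-depth mean intensity is subtracted, re-amplifying deep voxels.
3. **Volume pyramid + contrast enhancement** — the volume is downsampled
   2× per level in all three dimensions; coarse levels are trilinearly
   upsampled and voxel-wise multiplied into finer ones (normalized by the
   geometric mean), embedding the reliable macrostructure.
4. **Coarse-to-fine surface detection** — at each level, every A-scan is
   filtered with a set of kernel sizes inside a narrowing axial region;
   per line, the kernel whose candidate positions have the lowest weighted
   standard deviation over a small neighborhood wins; holes are collapsed
   by perimeter interpolation.
5. **Masking** — the fingertip area is found by comparing maximum
   intensities just above vs. just below the detected surface, then box
   blur + Otsu + flood-fill cleanup.
6. **Ridge envelopes** — smooth heightmaps touching only ridge tops
   (upper) or valley bottoms (lower), via a horizon search along both
   B-scan directions.
7. **Flattening** — scan lines are shifted up by the outer *envelope*
   plus the outer-layer height $\Delta S = \max(S - E_S)$, removing the
   outer fingerprint completely (flattening against the ridged surface
   itself would imprint a hybrid fingerprint on the deeper layers); the
   segmentation then runs a second time for the junction, and the shifts
   are reversed.
8. **2D conversion** —
   $\mathrm{FP2D} = \mathrm{clamp}\big((S - E_{up})/(E_{low} - E_{up}),\,0,\,1\big)$,
   ridges dark, valleys light.

Because real OCT fingertip scans are subject to data-protection
constraints, the package ships a synthetic phantom generator
(`generate_phantom()`, `phantom_preset()`) that emulates a curved ridged
fingertip with speckle and roll-off and provides exact ground truth, so the
entire chain is testable without scanner data.

## Worked example

```r
library(octseg)

# a synthetic fingertip with known geometry (quarter-size for speed)
spec <- phantom_spec(dims = c(128, 128, 128), contact_radius = 55,
                     apex_depth = 24, epidermis_depth = 40,
                     curvature_radius = 300, seed = 42)
phantom <- generate_phantom(spec)
phantom$volume
#> <oct_volume> 128 x 128 x 128 voxels, uint8, pitch 20 x 20 x 5.5 um

result <- run_pipeline(phantom$volume)
result
#> <pipeline_result> 128 x 128 lateral grid
#>   mask coverage: 53.5%
#>   inner below outer: 100.0% of masked lines
#>   total time: 3.4 s

surface_rmse(result$outer_surface, phantom$truth$outer, result$mask)
#> [1] 0.3649067
surface_rmse(result$inner_surface, phantom$truth$inner, result$mask)
#> [1] 0.9416823
mask_dice(result$mask, phantom$truth$contact)
#> [1] 0.9576401
ridge_frequency(result$outer_2d, result$mask)
#> [1] 0.04555431
```

The two RMSE values say the outer and inner surfaces were recovered to
about 0.36 and 0.94 axial voxels (2 and 5 µm at the default pitch); the
Dice coefficient says the detected fingertip area overlaps the true contact
area almost perfectly; and the dominant spatial frequency of the 2D output
(0.0456 cycles/px ≈ 22 px period) matches the phantom's configured 24 px
ridge period to within the spectral bin width. `write_pipeline_result()`
writes every stage's output (16-bit TIFF heightmaps, PNG masks and
fingerprints, a JSON run log) to a directory.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/octseg.R", package = "octseg"))') \
    run scan.raw --meta scan.raw.json --out outdir --to-500ppi
```

with exit codes 0 (ok), 2 (format error), 3 (processing error), and a
`phantom` subcommand for generating test volumes.

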