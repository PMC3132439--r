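---
title: "Reconstructing calibrated 3D models from serial histological sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing calibrated 3D models from serial histological sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stack3d)
```

## The problem

Serial sectioning turns a fixed organ — a mouse brain cut coronally on a
cryostat, a heart — into an ordered pile of thin 2D images. Putting those
images back together into a quantitative 3D model requires undoing the
damage done by the sectioning itself: each slice lands on its slide with an
arbitrary shift and rotation, carries smears and glare from mounting, and is
slightly deformed by cutting and fixation. stack3d implements a classical,
fully deterministic pipeline for this reassembly, aimed at chromogenic
histology (e.g. X-Gal staining of β-Galactosidase reporter activity), where
the readout is a colour on an RGB camera image rather than a calibrated
scanner intensity.

The five stages run in a fixed order, each consuming the previous stage's
contract:

1. **Cleaning** — user-chosen RGB colour ranges define the background;
   matching pixels become exact black `(0,0,0)`. From here on *tissue* means
   *not exactly black*, a predicate every later stage relies on.
2. **Centring** — the unweighted barycentre of the tissue pixels is moved to
   the bitmap centre by an integer shift.
3. **Orientation** — each section is rotated through all 360° on a fixed
   grid against its already-registered predecessor; the angle minimizing the
   summed absolute luminance difference wins.
4. **Deformation reduction** — the tissue boundary is encoded as a radial
   contour (distance from centre per angle), adjacent contours are averaged
   pairwise, and each section's interior is rescaled radially onto its
   corrected contour.
5. **Assembly and measurement** — sections become z-slabs of a voxel grid
   whose physical dimensions come from the calibration; tissue volume is the
   count of non-black voxels times the voxel volume, and blue-dominant
   voxels are isolated as molecular signal.

## Calibration model

Physical scale enters only through the stack manifest: a known tissue length
`L_w` (mm) spanning `n_x` pixels gives the in-plane voxel size
`X_rel = Y_rel = L_w / n_x` (square pixels are enforced to 1e-6 relative),
and the inter-section spacing `d_s` gives the slab depth `Z_rel = d_s`. With
15 µm sections and every fourth section stained, `d_s = 0.06` mm and the
voxels are strongly anisotropic; the exported MetaImage/NIfTI headers carry
that anisotropy exactly rather than resampling. No inter-slab interpolation
is performed: interpolation cannot add information, and at these spacings
the interpolation error is dominated by the mechanical reconstruction error.

## Design choices in the orientation metric

The difference metric is the L1 sum over all pixels of Rec. 601 luminance
differences (`0.299 R + 0.587 G + 0.114 B`, rounded; background black
contributes 0). A plain signed sum of intensity differences telescopes into
a difference of image totals and is constant over rotation, so it cannot
rank candidate angles; the absolute-value form is the minimal metric with
the intended behaviour, and a squared (SSD) variant is available as a
configuration option. Rotation uses inverse-mapped nearest-neighbour
resampling about the frame centre: nearest-neighbour keeps the exact-black
background predicate intact (no interpolated grey halo) and an inverse map
leaves no holes. The angular grid defaults to 1° (360 evaluations); ties are
broken toward the smallest wrapped angle, positive before negative, so a
rotationally symmetric section deterministically reports 0°.

Orientation is chained — each section aligns to the nearest preceding
retained section in registered form, the first retained section being the
unrotated anchor. Chaining matches how adjacent sections actually resemble
each other, but it has a measurable consequence: each link's angle is
quantized to the grid, so the *absolute* orientation of section `k` performs
a bounded random walk of quantization steps along the chain. What the
algorithm controls is the *per-link* alignment, and that is what
`evaluate_registration()` scores: the rotation error of a section is its
orientation residual differenced against the residual of the section it was
aligned to. Translation recovery is scored absolutely against the true
tissue barycentre, because centring is not chained.

A second consequence: centring places the *barycentre*, not the geometric
centre, on the rotation axis. For a cross-section whose centroid sits away
from its geometric centre, part of any rotation appears as a translation of
the centroid, and rotation alignment degrades. This is inherent to
barycentric centring; the phantom used for transform-recovery validation (a
cylinder with two unequal off-axis bores whose first moments balance) is
deliberately built so its centroid lies on the rotation axis while its
cross-section has no rotational symmetry, making recovery well-posed at
every slice.

## Deformation correction and its assumptions

The radial contour walks each of `m` rays (default
`max(360, ceiling(pi * max(H, W)))`, so adjacent rays are ≤ 1 px apart at
the border) from the frame border toward the centre and records the first
non-black pixel. The scheme is valid for star-convex sections: it sees only
the outermost tissue along each ray, and interior holes (heart ventricles)
are rescaled along with the interior rather than independently tracked —
an inherent limit of radial schemes, as opposed to active-contour models.
Smoothing is the forward pair average `L_n = (l_n + l_{n+1}) / 2` where both
sections hit at that angle; where only one hits, the original value is kept,
and the last section passes through unchanged (the boundary case has no
mandated behaviour; passing it through keeps the operation local). One pass
is the default; extra passes keep averaging toward a flatter profile. The
warp takes output polar coordinates `(rho, alpha)` to input radius
`rho * l_old / L_new` at the nearest grid angle — inverse mapping with
nearest-neighbour sampling, for the same reasons as rotation.

## The phantom generator

Because no public serial-section dataset with ground truth exists for this
workflow, validation is done on synthetic phantoms: a solid shape of known
geometry (sphere, ellipsoid, cylinder with optional bores, two-lobed sphere
union) sliced at its slab mid-planes `z = (k + 1/2) d_s` with no
partial-volume rendering, matching the pipeline's no-interpolation stance.
Each slice is then perturbed in a recorded order — rotation about the frame
centre, integer-pixel translation, sinusoidal radial deformation
`rho' = rho (1 + A sin(f alpha + phi))` with a per-slice random phase, then
background noise (glare spots and salt/pepper) — and rendered *analytically*
through the inverse of the composed transform, so the generated geometry is
exact rather than accumulated through resampling. Blue signal blobs are
spheres placed strictly inside the tissue with a clearance margin; a blob
pixel is only ever drawn where tissue exists, so signal ⊆ tissue by
construction and detection precision/recall are well defined.

The truth object records, per slice, the applied transforms, the true
tissue barycentre, the noise-free tissue and signal masks, and the analytic
shape and blob volumes. Fixing the seed makes the stack bit-identical.

What the phantom does **not** emulate: histological texture (tissue is a
flat grey tone), staining chemistry, illumination gradients, tears and
folds, or z-correlated deformation. Passing tests therefore demonstrate the
geometric and arithmetic correctness of the pipeline under its stated
assumptions, not robustness to every artefact of real slides.

### Default study conditions

The validation fixtures use conditions typical of small-animal cryostat
work: 20 µm (volume studies) or 15 µm (registration studies) in-plane
pixels, 50–60 µm slab spacing, organs of 2–4 mm extent, per-slice
translations up to 15 px and rotations up to 45°, 1% salt/pepper density on
the background, and a blue blob tone of `(40, 40, 120)` against `(128, 128,
128)` grey tissue — a blue dominance margin of 80, isolated at a margin
threshold of δ = 40. Problem sizes in the test-suite (80 × ~200² px for the
volume phantom, 40 × ~230² px for the registration phantom) were chosen so
the entire validation runs in minutes on one CPU while keeping boundary
pixelation below the tolerances being asserted.

## Numerical conventions and degenerate inputs

* Rasters are `H × W × 3` integer arrays, 0-based pixel coordinates,
  top-left origin, x rightward, y downward; angles in degrees from +x
  toward +y; the frame centre is `((W-1)/2, (H-1)/2)`.
* Cleaning lifts a surviving input pixel that is exactly black to
  `(1,1,1)` — visually lossless, but it keeps genuinely black tissue from
  being silently reclassified as background. Cleaning is idempotent
  whenever exact black itself falls inside a supplied background range (the
  usual case; the test fixtures always include a dark range).
* An all-black (empty) section is an error for centring and contour
  extraction; callers mark such sections excluded instead. Excluded
  sections stay in the stack, are skipped by registration and smoothing,
  and their slab is filled from the nearest retained section (ties to the
  earlier one), keeping the z-axis physically uniform.
* Contour rays that meet no tissue are flagged and contribute nothing to
  smoothing; warping copies pixels through unchanged at angles without
  contour information.
* Enclosed cavity volume (ventricle-chamber-like measurements) is defined
  per slab: background pixels not 4-connected to the frame border, stacked
  across slabs. This is the minimal completion consistent with measuring
  chamber volumes on a slab-wise reconstruction; a full 3D 6-connected
  flood would additionally treat cavities open only through the top or
  bottom face as exterior.
* The blue-dominance rule `B ≥ R + δ AND B ≥ G + δ` uses raw 8-bit channel
  values and a non-strict inequality, so δ = 0 deterministically flags any
  voxel whose blue channel at least ties both others.

## Known limitations

Star-convexity of cross-sections is assumed by the contour stage; highly
concave sections will have their concavities bridged. Sub-degree and
sub-pixel registration refinement is out of scope, as are affine/elastic
registration, mutual-information metrics, colour deconvolution, and
interactive rendering — exports to MetaImage/NIfTI hand the model to any
standard volume viewer.
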