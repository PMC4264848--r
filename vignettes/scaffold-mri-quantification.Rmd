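---
title: "Quantifying tissue in scaffold micro-MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue in scaffold micro-MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scaffoldMRI)
```

## The problem

Micro-MRI can watch tissue grow inside opaque 3D polymer scaffolds
without sectioning or staining: scaffold polymer appears dark, the
buffer filling the pores grey, and lipid-containing cell/ECM material
bright. At low cell densities, however, the useful contrast between
tissue and buffer is smaller than the smooth spatial drift of the
background signal caused by coil and field inhomogeneity. A single
global threshold — the natural segmentation for three well-separated
intensity classes — then fails: somewhere in the slice the brightened
buffer outshines the dimmed tissue.

`scaffoldMRI` implements the post-imaging sequence that repairs this,
plus everything needed to turn the segmented stacks into numbers and
3D models, and a synthetic phantom generator that makes the whole
chain testable with known ground truth.

## The processing model

For a stack $I_k(x,y)$ of slices, the sequence is:

1. **Background estimation.** A reference slice $I_r$ containing only
   buffer (the first or last slice of the stack, above or below the
   scaffold) is opened with a disk structuring element of radius 9 px:
   $B = (I_r \ominus D_9) \oplus D_9$. Opening removes bright
   structures smaller than the element and keeps the smooth
   background; it is anti-extensive ($B \le I_r$) and idempotent.
2. **Subtraction.** $I_k' = \max(I_k - B, 0)$ for every slice $k$ —
   one 2D background for the whole stack. The clip at zero keeps
   downstream thresholding on a non-negative scale.
3. **Denoising.** A 2D median filter over a disk of radius 2 px
   (13 pixels), slice by slice.
4. **Segmentation.** Inside a circular region of interest (ROI)
   enclosing scaffold and surrounding liquid: tissue is
   $I_k' \ge t$, followed by a binary opening with a radius-2 disk to
   remove outlier pixels; scaffold is $I_k \le s$ on the *raw* stack
   (the dark class — background subtraction is tuned for the bright
   class and would erase it).
5. **Threshold calibration.** $t$ is not free: it is the smallest
   threshold at which a *bare* scaffold scan (no cells), processed
   identically, shows at most a fraction `fp_tolerance` (default
   0.001) of its pore pixels as false-positive tissue. The
   false-positive count is monotone non-increasing in $t$, so a
   binary search over the observed intensities is exact.
6. **Quantification.** Per slice, with all counts inside the ROI:
   $\text{pore} = \text{ROI} - \text{scaffold}$ and
   $\text{tissue\%} = 100 \cdot \text{tissue}/\text{pore}$.
   Slices are grouped into top/middle/bottom sections (equal thirds
   of the slice range that contains scaffold, unless overridden);
   sections are summarised as mean ± sample SD and compared by
   one-way ANOVA with Bonferroni-adjusted pairwise pooled-variance
   t-tests (stars at p < 0.05/0.01/0.001). A 4-stage projection map
   counts, per pixel, in how many of a section's slices it was
   tissue, binned into four equal-width stages (stage 0 = never).
7. **Surface models.** Binary masks become triangulated surfaces at
   iso-level 0.5 (scaffold at full resolution, tissue downsampled by
   2, mirroring coarser meshing of the second object), smoothed with
   a non-shrinking Taubin filter.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `se_radius` | 9 | px | background-opening disk radius |
| `median_radius` | 2 | px | median-filter disk radius |
| `opening_radius` | 2 | px | mask-smoothing opening radius |
| `fp_tolerance` | 0.001 | fraction | allowed bare-scaffold FP signal |
| `scaffold_threshold` | 50 | intensity | upper bound of the dark class |
| `reference_slice` | last | index | background reference slice |
| `factor_scaffold` / `factor_tissue` | 1 / 2 | — | mesh resampling |
| `taubin_lambda` / `taubin_mu` / iterations | 0.5 / −0.53 / 10 | — | smoothing |

The morphology radii are the method's standard settings. The
structuring element is the set of pixels whose centre lies within the
radius (a radius-2 disk holds 13 pixels); a consequence worth knowing
is that an opening with a disk always rounds convex corners — a 5 × 5
square keeps its core but loses its corners. All morphological and
median operations use symmetric (mirror) border padding, the common
imaging-toolbox default, which also keeps the brute-force test oracle
simple. `scaffold_threshold` defaults to midway between the phantom's
scaffold and liquid levels; on real scans it must be set per
experiment, like the tissue threshold's calibration.

## The phantom: what it emulates, what it does not

`build_phantom()` renders a known ground truth into an MRI-like stack:

* **Geometry.** A cylindrical 0°/90° woodpile lattice, 8 mm diameter
  × 3 mm height, fiber spacing 1 mm, fiber diameter 0.2 mm, layer
  thickness 0.15 mm (layers fuse vertically), centred in a 10 mm
  field of view at a 128×128 matrix, 45 slices of 0.07 mm. The first
  and last slices are liquid-only so a background reference always
  exists.
* **Tissue.** Structures are placed in the pore space per section
  until a target share of the pore volume is reached: `string`
  (ball-dilated random walks, the morphology seen in cultured
  constructs), `blob` (spheres), or `sheet` (a connected layer
  hugging a section's bottom). Structures keep one ball radius of
  clearance from the scaffold so voxelisation never shaves them into
  slivers; the final stamp is trimmed to land on the target count
  (the generator contract is ±10 % relative). Tissue never overlaps
  scaffold.
* **Intensity.** Class levels 20/100/160 (scaffold/liquid/tissue,
  arbitrary units) in native contrast; agent contrast (85/100/220)
  emulates an iron-oxide agent collapsing scaffold–liquid contrast —
  the pore-closure failure mode. Levels are scaled by $1 + B(x,y)$
  with $B$ a seeded random second-order polynomial spanning exactly
  $[-a, +a]$ *across the sample tube* (the physically meaningful
  region; an optional Gaussian random field component with a
  configurable correlation length can be added). Gaussian noise
  (σ = 5, i.e. 5 % of the liquid level) is the default; Rician is
  available. Rendering is deterministic per seed.

The phantom is phenomenological: it has no relaxation-time physics,
no partial-volume averaging at class boundaries, no slice-profile or
ghosting artefacts, and its bias field is smoother and more regular
than a real coil pattern. Passing the recovery tests therefore shows
the *processing chain* is correct and self-consistent — not that any
particular scanner's data will be recovered with the same accuracy.

## Numerical choices and degenerate inputs

* Grayscale morphology runs through EBImage with explicit symmetric
  padding (EBImage's own borders are not otherwise pinned down) and
  intensity normalisation to `[0, 1]` and back, since erosion and
  dilation commute with positive scaling.
* Subtraction promotes to float and clips at zero; no integer
  wraparound is possible.
* A fully occluded slice (zero pore pixels) is an error, never a
  silent zero. An all-dark stack fails ROI fitting with a request for
  a manual ROI. An empty volume meshes to an empty mesh.
* The opening of a *curved* background has an inherent residual: a
  smooth intensity peak narrower in curvature than the structuring
  element is clipped slightly, so corrected liquid does not sit at
  exactly zero under strong bias. The calibration absorbs this —
  which is exactly how the original procedure works.
* Surfacing uses marching tetrahedra (Kuhn 6-tetrahedron cube
  decomposition): watertight by construction, no ambiguous cube
  cases, exact mid-plane surfaces on flat binary boundaries. Nodes
  exactly at the iso-level are nudged below it; zero-area faces are
  dropped. Triangles are oriented outward by checking each normal
  against the tetrahedron's inside corners.
* The 4-stage bins are equal-width over `1..n` with upper edges
  `ceiling(k*n/4)`; for degenerate section lengths (n < 4, where
  edges collide) a full count is still assigned the top stage.
* Stacks are written 16-bit with explicit rounding (the TIFF writer
  truncates), making phantom round-trips bit-exact.

## Design decisions where the method was open

* **One background per scan**, taken from a single reference slice
  and subtracted from every slice. Per-slice backgrounds would also
  be defensible; they are available by calling
  `approximate_background()`/`subtract_background()` per slice, but
  the pipeline does not claim that variant.
* **Scaffold is segmented on the raw stack.** Background subtraction
  is designed for the bright class; on the corrected stack the dark
  class collapses into the clipped zeros. Consequently the tissue and
  scaffold thresholds live on different intensity scales, and
  disjointness of the two masks is enforced directly when they are
  bundled.
* **False positives are counted after the binary opening** during
  calibration, because post-opening pixels are what the
  quantification counts as signal; counting before opening is a flag
  (`count_after_opening = FALSE`).
* **Bonferroni** is applied to the three pairwise section
  comparisons, each a pooled-variance two-sample t-test with its p
  multiplied by the number of comparisons and capped at 1.
* **Section boundaries** default to equal thirds of the informative
  (scaffold-bearing) slice range, which on the default phantom
  reproduces the generator's own sections exactly.

## Problem sizes used by the tests

The structural unit tests run on 64 × 64 × 32 phantoms (same scaffold
geometry, coarser grid); accuracy contracts — occupancy recovery
within ±0.5 percentage points over the 1–4 % regime, mesh volume
within 10 % of the voxel volume — are asserted at the acquisition
resolution (128 × 128 × 45), where tissue structures span several
voxels, across three seeds. Morphology is audited against a
brute-force erosion/dilation oracle on 200 random 16 × 16 images for
radii 1–3. `scripts/acceptance.R` re-runs the full chain at the
128-matrix conditions and writes its headline numbers as JSON.

## Known limitations

* Accuracy is resolution-bound: at coarse grids (fibers ≈ 1 px) the
  radius-2 opening and the mesh chamfer bite a visibly larger share
  of thin structures; the stated tolerances hold at the 128-matrix
  acquisition geometry.
* The automatic ROI fit assumes the liquid region is the largest
  bright connected component of a mid-stack slice; unusual tube
  placements need a manual ROI.
* Downsampling by block mean before surfacing can dissolve structures
  thinner than the factor (a factor-2 tissue mesh of a 1-px-thin
  structure is legitimately empty).
* The ANOVA treats slices as independent replicates, as the
  original analysis does; spatial autocorrelation between adjacent slices
  is not modelled.
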