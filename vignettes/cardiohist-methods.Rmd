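---
title: "Quantifying structural remodeling in cardiac histology with cardiohist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structural remodeling in cardiac histology with cardiohist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiohist)
```

## The problem

Structural remodeling of the myocardium — fibrosis accumulating between
individual cardiomyocytes, myocyte hypertrophy, capillary rarefaction,
fibroblast proliferation — is a substrate for atrial fibrillation and other
cardiac disease, and is classically quantified by hand from stained tissue
sections, at a cost of hours per image. cardiohist automates this
quantification from calibrated three-channel fluorescence micrographs of
*transversely* sectioned myocardium:

* **WGA channel** (wheat germ agglutinin, membrane + extracellular matrix):
  overall fibrosis fraction, myocyte count and size, endomysial septum
  widths, the per-cell cardiomyocyte dissociation index (CDI), and the
  spatial clustering of enhanced endomysial fibrosis;
* **endothelial channel** (CD31 in human, GS-IB4 in animal tissue):
  capillary count, size and per-myocyte density;
* **vimentin channel**: fibroblast count per myocyte, after subtracting the
  endothelial mask to remove vimentin's known cross-reactivity with
  endothelium.

All measurements are reported in micrometres using a user-supplied
calibration in pixels per millimetre (`1000 / resolution_px_per_mm`
micrometres per pixel; square pixels assumed, anisotropic inputs rejected).
Coordinates in all outputs are 0-based pixel indices, origin top-left,
x = column.

## The WGA pipeline

1. **Local adaptive thresholding.** WGA-positive pixels are delineated with
   the Phansalkar threshold, designed for low-contrast stained images:
   a pixel is positive when its intensity exceeds
   $t = m\,(1 + p\,e^{-q m} + k(s/r - 1))$, with $m,s$ the mean and standard
   deviation over a disk of radius `phansalkar_radius_px` (default 15 px;
   it should scale with magnification), and $k = 0.25$, $r = 0.5$, $p = 2$,
   $q = 10$ — the widely used defaults of the algorithm's common
   implementation. Boundaries are handled by mirror padding. The fibrosis
   fraction is simply the fraction of WGA-positive pixels.

2. **Seed detection.** The intensity plane is Gaussian-blurred
   (`blur_sigma_px`, default 2 px) and cell seeds are the regional minima
   with *dynamic* (prominence) at least
   `contrast_scale` × (mean WGA-positive − mean WGA-negative intensity),
   default `contrast_scale = 0.5`. The image's own stain contrast thus sets
   the detection prominence, making one parameter serve differently exposed
   images. Minima of sufficient dynamic are found as the regional minima of
   the h-minima transform (morphological reconstruction by erosion of
   $f + h$ over $f$); plateaus are merged to their centroid. A candidate
   whose surrounding annulus (radii 2–6 px) is more than 60 % WGA-positive
   is rejected: it is a dim pocket inside a fibrotic patch, not a myocyte.

3. **Voronoi watershed.** Surviving seeds grow into regions over the blurred
   intensity (EBImage's Voronoi-metric propagation), tiling the image; each
   region clipped to the WGA-negative space is one myocyte. Size is the
   **minimal Feret diameter**, the smallest caliper width over all
   directions — under approximately transverse sectioning it underestimates
   the true cross-section only slightly and systematically, unlike the
   maximal width. It is computed exactly on the convex hull of the region's
   pixel corners (minimal width of a convex polygon is attained
   perpendicular to a hull edge), so a 10-px-wide axis-aligned bar measures
   exactly 10 px. Regions touching the border (clipped, biasing Feret low)
   or below `min_cell_area_um2` (20 µm²) are excluded from size statistics
   but remain nodes of the neighbour graph.

4. **Neighbour graph and septum widths.** Two myocytes are direct
   neighbours when their watershed regions share a boundary of at least
   `neighbor_min_contact_px` (5) 4-connected contact pixel pairs; regions
   that merely touch at a mosaic corner do not share a septum and are not
   neighbours. For each neighbour pair the WGA mask is sampled at
   `septum_step_px` (0.25 px) steps along a profile line, and the septum
   width is the length of the contiguous WGA-positive run containing the
   boundary crossing, clipped where the run strays into a third cell's
   territory (at triple corners neighbouring septa merge). Two refinements
   make this measurement sub-pixel accurate:

   * With `obliquity_correction = TRUE` (default) the profile is taken
     *perpendicular to the septum* — through the middle of the shared
     boundary, along the normal of its principal axis — rather than along
     the raw seed-to-seed chord. A chord crossing the septum at angle
     $\theta$ overestimates the width by $1/\cos\theta$, and near corners
     by much more; measuring across the septum at its midpoint removes
     both effects. The raw chord profile (the classical "line selection
     between the local minima") is available by switching the flag off.
   * The run's endpoints are refined to the sub-pixel crossing of the
     intensity half-maximum between the septum peak and the adjacent
     interior level. The binary mask locates the septum, but its edge is
     only pixel-accurate, and the exact position of the adaptive threshold
     within the stained-to-unstained transition would otherwise bias every
     width by a few tenths of a pixel.

   `septum_profile = "fwhm"` replaces the thresholded run entirely by the
   full width at half maximum of the raw intensity profile.

5. **CDI and clustering.** An inter-myocyte distance is *enhanced* when it
   exceeds a reference mean by more than two standard deviations
   (`reference_mu_um`, `reference_sd_um`; supplied in the configuration for
   cross-study comparability, or estimated by pooling all measured edges of
   a designated reference image set — sample SD, $n-1$). Each cell's CDI is
   the fraction of its septa that are enhanced: 0 for a cell closely
   apposed to its neighbours, 1 for a fully dissociated cell. Cells without
   neighbours are flagged undefined and excluded from the image mean.
   Spatial clustering of enhancement is measured on the subgraph of
   enhanced edges as the average local clustering coefficient
   ($2T_v / (d_v(d_v-1))$ for degree $\ge 2$, else 0, averaged over **all**
   cells). The null model holds the tissue geometry fixed and shuffles the
   multiset of measured widths over the edges (1000 permutations by
   default): the permutation mean is the expected clustering coefficient,
   and the p-score is the proportion of permuted coefficients *strictly*
   smaller than the observed one. A p-score near 1 means enhanced septa
   clump spatially more than a random reassignment of the same widths
   would produce.

## Colour channels

Capillaries and fibroblasts are segmented by a Gaussian blur followed by an
HSB colour threshold (hue within a circular interval, saturation and
brightness above floors; defaults: green hue 80–160°, blue hue 200–280°,
floors 0.15). Capillary particle analysis keeps 8-connected components of
at least 1.5 µm²; **all** surviving components count towards the capillary
count, and only components with circularity $4\pi A / P^2 \ge 0.35$ —
transversely cut capillaries — are additionally sized by minimal Feret.
Perimeter is estimated from the boundary chain with the
Vossepoel–Smeulders corner-corrected weights (0.980 per axis step, 1.406
per diagonal, −0.091 per direction change), which is asymptotically
unbiased for smooth shapes, so digitised-disk circularity converges to 1
with radius; the plain √2-weighted chain converges to ≈ 0.90 and would make
the 0.35 gate mean something different at different magnifications.
Fibroblasts are components of (vimentin AND NOT endothelial) after the same
size gate — the subtraction removes cross-reactive endothelial vimentin
staining, and its order is fixed. Densities are count ratios per myocyte
(robust under hypertrophy, unlike per-area density); capillaries per mm²
is also emitted.

## Validation tools

Automatic detections are matched to manual annotations one-to-one by
greedy globally-minimal centroid distance ($d = \sqrt{\Delta C_x^2 +
\Delta C_y^2}$), capped at `match_max_dist_px` (default: half the median
myocyte minimal Feret — an uncapped match would pair distant spurious
objects). Greedy matching is deterministic and, at histology densities,
agrees with the exhaustive minimum-cost assignment (the test suite checks
this against an enumeration oracle). From TP/FP/FN follow sensitivity
TP/(TP+FN), precision TP/(TP+FP), FNR FN/(FN+TP) and F1
2TP/(2TP+FP+FN); paired size measurements are summarised by a
Bland–Altman mean relative difference with a t-based 95 % CI. Pearson
correlation and a two-way mixed absolute-agreement ICC are thin
conveniences over the standard formulas.

## The synthetic tissue generator

Because no annotated reference micrographs are distributed with the
package, every pipeline stage is validated against synthetic transverse
myocardium with exhaustive ground truth (`synthetic_spec()`,
`generate_tissue()`):

* **Geometry.** Poisson-disk seeds (spacing the larger of
  $0.7\sqrt{A/n}$ and 0.6 cell diameters) and their Voronoi mosaic model
  the transversely cut myocyte bundle. Defaults: 320 × 320 px at
  2000 px/mm (0.5 µm pixels, i.e. the 200–400× magnification range the
  method is designed for), 100 cells of nominal diameter 14 µm — realistic
  atrial myocyte cross-sections.
* **Septa.** Each neighbour pair draws a width from
  N(2.5 µm, 0.6 µm²) truncated at 0.3 µm (the 2.5–3.6 µm range reported
  for atrial endomysial fibrosis), optionally widened inside a planted
  *enhanced patch*. Membranes are rendered as bands of exactly that width
  around each Voronoi edge, using the exact pixel-to-bisector distance
  $(d_1+d_2)(d_2-d_1)/2L$, with a 1-px anti-aliased edge so sub-pixel
  width recovery is meaningfully tested. Ground-truth edges require the
  pair's bisector to be realised over at least 8 pixels: pairs sharing
  only a sliver of boundary are engulfed by neighbouring septa's corners
  and never realise their drawn width.
* **Colour channels.** Capillaries are bright disks (mean 15 µm²) at
  three-cell corners — inside the WGA-positive septa, as anatomically
  appropriate — spaced at least 5 radii apart so blur cannot merge them;
  fibroblasts are irregular blue blobs in the interstitium, a configurable
  fraction of which is rendered *inside* capillaries to emulate
  endothelial vimentin cross-reactivity (they must vanish under
  subtraction). Gaussian noise is added last; membrane contrast is 0.8, so
  `noise_sigma = 0.04` is 5 % noise.

What the generator does **not** emulate: longitudinally or obliquely
sectioned fibres, perimysial bundle anatomy, illumination gradients,
point-spread blurring, chromatic shift, or channel misregistration
(channels are pixel-aligned by assumption). Passing recovery tests on
these scenes therefore demonstrates the correctness of the measurement
machinery under the stated imaging model, not robustness to every
real-world artefact; the control overlays exist precisely so a user can
audit real images.

## Numerical choices and degenerate inputs

* 16-bit and 8-bit inputs are min–max normalised to [0, 1] per image at
  load, so one threshold parameter set serves both depths.
* Seed plateaus (ties in the blurred minima) merge to the plateau
  centroid; two centroids rounding to the same pixel keep the first.
* A fully fibrotic field (no minima) yields an empty record set, not an
  error; degenerate stain contrast (non-positive prominence) is an error.
* Collinear regions have minimal Feret 0 with a warning; metrics with
  empty denominators (no neighbours, zero myocytes, TP = 0 with no
  detections) are `NA`, flagged rather than fabricated.
* The permutation test is deterministic given its seed, restores the
  caller's RNG state, and flags the zero-enhanced-edge case as degenerate
  (p-score undefined). Ties count as not-smaller, per the strict
  inequality in the p-score's definition.
* Batch runs are a pure function of input bytes, configuration and seed;
  channels are matched across folders by case-insensitive base filename
  and orphan images are skipped with a warning.

## Test problem sizes

The test suite validates detection on twenty 100-cell mosaics at 5 %
noise, measurement fidelity and CDI recovery on noise-free 100-cell
scenes, null calibration of the clustering p-score on 200 simulated
width assignments (1000 permutations each) and power on 50 planted-patch
assignments — sizes chosen so the whole suite runs in a few minutes on a
single core while keeping Monte-Carlo error well below the tested
tolerances. `scripts/acceptance.R` re-runs the same study conditions end
to end from a single seed.

## Known limitations

* Minimal Feret under approximately transverse sectioning is a small,
  systematic *under*estimate of myocyte and capillary size; comparisons
  between groups measured the same way are unaffected.
* The septum width is measured on the thresholded mask; with the default
  sub-pixel refinement its residual error is ~0.3 px on synthetic scenes,
  but a genuinely out-of-focus or unevenly stained septum will still be
  measured at whatever width the stain presents.
* The CDI depends on the reference statistics; CDI values are only
  comparable across studies when the same reference (mean + 2 SD) is used.
* The clustering permutation test randomises measured widths over the
  *fixed* adjacency graph; it asks whether enhancement clusters given the
  tissue geometry, not whether the geometry itself is abnormal.
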