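---
title: "Quantifying plasmodesmata pit fields on cell interfaces in 3D"
author: "pdmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasmodesmata pit fields on cell interfaces in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmap)
```

## The measurement problem

Plasmodesmata are cytoplasmic channels through plant cell walls; they
cluster into *pit fields*, which a confocal microscope can resolve as
punctate fluorescence of a pit-field-localized marker protein, even though
individual channels are below its resolution. How much marker signal sits
on each cell--cell interface, how densely, and how clustered it is across
the wall are all biologically meaningful: they proxy the capacity and
geometry of symplastic transport between each specific cell pair.

`pdmap` turns a dual-channel 3D stack of a root (channel 1: cell-wall
stain; channel 2: pit-field marker) into a per-interface table of three
statistics:

* **Total Signal** \(S\): the binarized marker signal integrated over the
  interface patch, in \(\mu m^2\) of covered wall.
* **Signal Density** \(D = S/A\): coverage relative to the interface area
  \(A\).
* **Moran's I**: spatial autocorrelation of the binary signal over the
  patch mesh,
  \[
  I \;=\; \frac{N}{W}\,
  \frac{\sum_{ij} w_{ij}\,(x_i-\bar x)(x_j-\bar x)}
       {\sum_i (x_i-\bar x)^2},
  \]
  with \(w_{ij}=1\) when vertices \(i,j\) share a mesh edge. A perfectly
  alternating (checkerboard) pattern scores exactly \(-1\); a segregated
  half-and-half pattern approaches \(+1\) with grid size; clustered pit
  fields score higher than dispersed ones.

For between-sample comparison, \(S\) and \(D\) are divided by their sums
over all retained interfaces of a sample and expressed as percentages, so
each sample's values add to 100 regardless of expression level or imaging
settings.

## Pipeline

1. **Segmentation** (`segmentCells`): the wall channel is Gaussian-blurred
   with a physical radius (default 0.5 µm, converted to per-axis voxel
   sigmas, so anisotropic voxels are handled in µm throughout), then
   flooded by a seeded 3D watershed. Seeds are connected components of
   voxels below the `seedQuantile` intensity quantile (default 0.5);
   components touching the stack border are the mountant/exterior and
   become background. The watershed ridge settles on the bright wall, so
   labels meet mid-wall. `filterSmallLabels` absorbs fragments below
   `minCellVoxels` (default 50) into their largest-contact neighbour; it
   replaces the interactive proof-reading step of a microscope workflow.

2. **Interface meshing** (`buildInterfaceMesh`): the boundary surface of
   the label volume is extracted as voxel-face quadrilaterals
   (triangulated), so every triangle belongs to exactly one interface —
   the unordered pair of adjacent labels, with 0 for the exterior. This
   gives three invariants by construction: a cell's interface areas sum
   exactly to its surface area, the a--b and b--a patches are the same
   object, and mesh edges provide the adjacency graph used by Moran's I.
   The surface is then resampled to the requested `cubeSize` by
   patch-aware vertex clustering (vertices merge only with vertices
   belonging to the same set of interfaces, and the cluster takes the mean
   member position, which restores sub-voxel boundary placement; when the
   voxels are coarser than half the cube size the labels are first
   resampled to a cubeSize/2 lattice so there is something to average).
   Finally 10 smoothing passes are applied; each pass is a Taubin
   \(\lambda|\mu\) cycle (a step of 0.5 toward the neighbourhood mean,
   then \(-0.53\) away), which flattens the voxel staircase without the
   surface shrinkage a plain Laplacian would cause. Vertices on the
   junction line between patches average only along vertices of the same
   junction, and corner points stay fixed, preserving cellular
   connectivity. Abundance analyses use `cubeSize = 0.5` µm; Moran's I
   uses a finer 0.2 µm mesh, whose vertex count scales accordingly.

3. **Annotation** (`annotateSample`): the organ axis is the first
   principal direction of the foreground voxels (an anisotropy ratio of at
   least 1.5 between the first two principal standard deviations is
   required — a stubby crop has no meaningful axis). Cells are typed by
   radial distance of their centroid in the axis frame: sorted radii are
   split at the largest gaps into as many bands as layer names
   (epidermis, cortex, endodermis, ...), outermost first — the
   radial-coordinate typing used for radially symmetric organs. Each
   interface is classified by its area-weighted mean normal against the
   local cylindrical frame: **apical--basal** (normal along the axis,
   i.e. transverse walls), **radial** (normal away from the axis,
   typically between layers) or **circumferential** (within a ring); if
   the top two |dot products| differ by less than 0.05 the interface is
   `unclassified` and excluded from class statistics. Interaction classes
   are alphabetical layer pairs ("cortex–endodermis"), collapsing
   same-layer pairs.

4. **Projection and trim** (`projectSignal`, `trimBackground`,
   `binarizeSignal`): each vertex samples the marker stack by trilinear
   interpolation along its normal within ±0.5 µm (steps of at most half a
   voxel) and keeps the maximum — pit fields are punctate and a max is
   robust to the exact wall offset (a mean aggregator is available). The
   background trim threshold for a vertex on a wall whose deeper cell is
   in layer \(\ell\) is \(T_0 f^{\ell}\): the geometric decay \(f\)
   (default 0.8) compensates photobleaching and depth attenuation in real
   stacks. Surviving signal is binarized to `maxValue` (default 1).

5. **Quantification and reporting** (`quantifySample`,
   `summarizeClasses`, `compareGroups`): exterior interfaces and
   interfaces smaller than 3 µm² are removed (the boundary value 3 µm² is
   kept — the rule removes interfaces *smaller than* the threshold),
   percentages are normalized per sample, Moran's I is computed per patch
   on the fine mesh (patches with all-0 or all-1 signal have no defined I
   and are excluded from I summaries but keep their S and D). Classes are
   compared with Welch's two-sample t-tests — group sizes and variances
   differ across interface classes, so the unequal-variance form is the
   defensible default — each interface counting as one observation, and
   annotated with the star ladder \(p<0.01\) (*), \(p<0.005\) (**),
   \(p<0.001\) (***). No multiple-testing correction is applied by
   default, mirroring common practice for these figure panels;
   `stats::p.adjust` can be applied to the returned p values when wanted.

## The synthetic root generator

No public dataset accompanies this type of experiment, so the package
ships a generator whose output has closed-form ground truth, and every
pipeline stage is validated against it.

The synthetic organ is a straight cylinder along z: concentric layers
(outer radii strictly decreasing; defaults 16, 11, 6 µm for epidermis,
cortex, endodermis), each split into angular sectors (8 per ring) and
axial segments (12 µm cells), rasterised at 0.25 µm voxels into a
~144×144×192 stack. The default proportions give 96 cells and an
elongation (axial sd / radial sd ≈ 2) comfortably above the axis
detector's anisotropy requirement, like a meristem crop imaged along the
root. Analytic areas are exact: apical--basal walls are annular sector
discs \(\tfrac{\Delta\theta}{2}(R_o^2-R_i^2)\), circumferential walls are
radial rectangles \((R_o-R_i)\Delta z\), and between-layer walls are
cylindrical patches \(R\,\Delta\theta\,\Delta z\).

The wall channel marks the two voxels astride every label-change face —
a symmetric band around the true boundary, so the watershed ridge is not
biased to either side — at amplitude 100, blurred with a 0.2 µm PSF proxy
and Gaussian noise (sd 2). The marker channel draws per-patch spot counts
from a Poisson law with mean `ratePerArea[class] × area`; the default
rates 0.4 : 0.1 : 0.1 µm⁻² (apical-basal : radial : circumferential)
encode the abundance ranking reported for root tissue, with apical--basal
walls carrying the most signal. Spots are placed uniformly on the patch
or by a Thomas cluster process (Poisson parents, Poisson offspring
displaced by an in-plane Gaussian of sd `clusterSigma` and clamped to the
patch; by default the parent intensity is derived as rate/offspring so
both modes share the same expected count — the property that makes paired
clustering comparisons meaningful). Each spot renders as an isotropic 3D
Gaussian (σ 0.15 µm, diffraction-scale) plus additive Gaussian noise.

What the generator deliberately does **not** emulate: optical anisotropy
along z, depth-dependent attenuation and photobleaching, cell-shape
irregularity, root curvature, and shot (Poisson) noise. Passing the
recovery suites therefore demonstrates correctness of the geometry,
projection and statistics under ideal imaging, not robustness to every
artefact of real microscopes; the trim decay `layerDecay` exists for real
data but is calibrated to 1 on synthetic stacks, which have no depth
attenuation (the noise floor is flat). Likewise the default trim
percentile (97.5th of the marker stack) is a heuristic for sparse real
signal — on synthetic data the tests set the trim explicitly to five
noise standard deviations, the principled choice when the noise level is
known.

## Numerical choices and edge cases

* **Seeds and background**: seed components smaller than
  `minSeedVoxels` are discarded (noise minima); losing no true cell
  requires this to stay below the smallest cell's eroded interior (~70
  voxels for the default endodermis wedges, hence the default 50).
* **Watershed ties** break in FIFO order (stable, deterministic floods).
* **Gaussian kernels** truncate at 5σ (tail mass < 1e-6) and renormalise
  at array edges, so constants are preserved exactly.
* **Area filter boundary**: interfaces with area exactly 3 µm² are kept.
* **Moran's I** is computed as `(N·num)/(W·den)` in one division so the
  checkerboard anchor is exactly −1 in floating point; constant patches
  return NA with reason `"no variance"` rather than 0.
* **Degenerate inputs**: empty label volumes, zero-signal samples, cells
  fewer than layers, and zero-area patches raise errors rather than
  propagate NaNs.
* **Mesh-resolution consistency** (areas at cube 0.2 vs 0.5) is asserted
  on a 0.125 µm rasterisation: at 0.25 µm voxels the residual difference
  is label quantisation (the 0.2 mesh cannot know where within a voxel
  the boundary lies), not a property of the meshing itself.

## Problem sizes used in the test-suite

The validation suites run on two fixtures chosen to exercise every code
path at desk scale: the default 96-cell root (0.25 µm voxels,
144×144×192) for segmentation recovery (exact cell count, per-cell IoU ≥
0.95) and the 7% interface-area oracle, and a 40-cell two-layer root
(88×88×128) for the projection, clustering and orientation recovery
properties, including 20 paired Thomas-vs-uniform seeds for the Moran's I
contrast and 5 seeds for the 4:1:1 abundance-ranking recovery. The
permutation test of the Moran randomization expectation −1/(N−1) uses
10,000 permutations on a 60-node graph.

## Known limitations

* The root axis is a single global PCA direction; strongly curved crops
  should be split into near-straight pieces.
* Layer typing by radial gap clustering assumes complete rings; partial
  crops with missing sectors can shift the gap structure.
* Interface areas inherit the label rasterisation: at 0.25 µm voxels,
  per-patch areas are accurate to a few percent (7% is the tested bound
  on the default geometry), and patches a few voxels across should be
  interpreted with care — the 3 µm² filter removes the worst of them.
* Total Signal is a proxy: binarized marker coverage, not a count of
  plasmodesmata; confocal resolution cannot separate channels within a
  pit field.
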