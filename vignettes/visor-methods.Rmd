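---
title: "Methods: oblique on-the-fly imaging, reconstruction and activation statistics"
author: "visor package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oblique on-the-fly imaging, reconstruction and activation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visor)
```

## The measurement model

`visor` implements the computational side of volumetric imaging with
synchronized on-the-fly scan and readout (VISoR): a cleared 300-µm
tissue slice moves smoothly under a pair of objectives while a thin
excitation beam, synchronized with the camera readout, sweeps an imaging
plane tilted 45° to the sample surface. Because each voxel is
excited for only ~100 µs, motion blur is `stage speed × exposure`
(≈ 0.05 µm at 0.5 mm/s) rather than the full inter-frame travel, and the
system acquires undistorted oblique sections continuously.

All downstream processing rests on one coordinate convention
(`oblique_to_world()`): world coordinates in µm, right-handed, with
x = stage travel, y = beam width, z = depth (decreasing into the
tissue); pixel and frame indices 0-based. A frame pixel (row r, column
c) of frame f maps to

\[
x = o_x + f\,s_f + r\,p\cos\theta,\qquad
y = o_y + c\,p,\qquad
z = o_z - r\,p\sin\theta
\]

with p the in-plane pixel size (camera pitch / effective magnification),
\(s_f\) the stage travel per frame (speed / scan rate) and θ the tilt.
The axial sampling step perpendicular to the image plane is
\(s_f\sin\theta\): 1 mm/s at 200 Hz and 45° gives the native
0.49 × 0.49 × 3.5 µm³ grid. The mapping is affine and inverted exactly
by `world_to_oblique()`; deskewing a column (`stack_column()`) is
trilinear resampling through that inverse. The axial anisotropy is
deliberately kept in the deskewed output rather than isotropized —
detection operates per-plane and the anisotropy is part of the native
data.

## The phantom generator — and what it does not emulate

Because raw data for this kind of instrument are terabyte-scale and not
publicly deposited, every stage of the package is exercised on synthetic
phantoms with exact ground truth (`phantom_spec()`, `render_phantom()`):

* **Somata/nuclei** are additive anisotropic Gaussians truncated at 3σ
  with σ = radius/2, so a matched band-pass (DoG) detector peaks at the
  centre. Default soma radius 5 µm, nucleus radius 4.5 µm, peak 900–1500
  counts on a 100-count tissue background — mid-range for
  fluorescent-protein and antibody labels in 16-bit data.
* **Noise** is Poisson shot noise followed by Gaussian read noise
  (σ = 2 counts default), the standard sCMOS model.
* **Placement** uses a jittered lattice (pitch 22 µm, jitter ±2 µm), so
  any two same-channel centres are ≥ 18 µm apart. That floor is the
  resolution limit of the default detector scale (two blobs closer than
  twice the effective DoG width merge into one response); placing cells
  closer would make the printed-count recovery experiments measure the
  point process rather than the detector. Colabelled nuclei sit exactly
  at their partner's centre.
* **Acquisition simulation** (`simulate_acquisition()`) samples oblique
  planes by the inverse shear mapping with trilinear interpolation,
  tiles columns along y with 10% overlap, and adds a stage lead-in so
  the deep wedge of the volume is covered. Unsynchronized mode averages
  sub-positions across the frame period — a box kernel whose width
  equals the inter-frame travel, reproducing the on-the-fly light-sheet
  smear that synchronized scanning eliminates.
* **Slice cutting** (`cut_and_deform_slices()`) splits the volume into
  thick slabs and applies to each an independent smooth in-plane
  deformation (≤ 5 random-phase sinusoids, wavelengths at or above the
  slice extent) plus an optional planar surface tilt, all recorded for
  scoring. The wavelength floor encodes the physics of slice handling:
  real distortions of cleared sections are large-scale bends with local
  strain of a few percent, not short-wavelength ripples. Fields are
  stored as backward maps, so inverting a recorded field is exact and
  forward-deforming a point is a fixed-point iteration.

What the phantoms do **not** emulate: optical PSF structure beyond the
Gaussian beam width, scattering and index-mismatch aberration, vascular
shadows, autofluorescence gradients, or fibre-tract texture. Passing the
recovery experiments therefore demonstrates correctness of the
*computations*, not robustness to every artefact of real tissue.

## Column stitching

Adjacent columns overlap by ~10%. `estimate_pair_offset()` estimates the
residual offset of each overlapping pair by background-subtracted
normalized cross-correlation restricted to the nominal overlap, with FFT
phase correlation as initialization and an integer-voxel NCC refinement
(±2 voxels). Sub-voxel stitching is intentionally out of scope: the
downstream consumers (cell detection, counting) are voxel-scale.
Overlaps thinner than 16 voxels, or scores below 0.3, fall back to the
nominal stage coordinates with a low-confidence flag. `solve_global_offsets()`
does a score-weighted least squares over the offset graph with the first
column of each connected component anchored at its nominal origin;
`fuse_columns()` blends with separable linear feather weights spanning
the full overlap, making the output a convex combination of the inputs.

## Four-step serial-slice reconstruction

1. **Surface flattening.** The face height map is the first voxel above
   an Otsu threshold per (x, y) column, median-filtered 3×3 (the
   threshold rule and filter are our choices; nothing in the protocol
   prescribes them), fitted with a least-squares plane over unmasked
   support; masked structures (ventricles) are interpolated from the
   plane. `flatten_slice()` resamples every column so both faces become
   constant-z planes, linear in between.
2. **Correspondences.** `extract_correspondences()` is a pluggable
   dense-correspondence stage. The default backend is coarse-to-fine
   block matching on gradient-magnitude images: a 4× coarse pass with
   doubled patch context resolves large offsets unambiguously, a
   full-resolution pass refines within ±5 px, and a parabolic fit on
   the NCC surface gives sub-pixel displacements. Correspondences are
   sampled on a regular grid restricted to high-texture locations;
   confidence is the local NCC. An exact SIFT-flow reimplementation is
   deliberately not attempted — the flow backend is a component, not the
   contribution, and any function with the same signature can be
   plugged in.
3. **Joint adjustment.** `adjust_correspondences()` minimizes
   \(\sum_i\|d_i-\hat d_i\|^2 + \lambda_{smooth}\sum_{(i,j)\in N}w_{ij}\|\hat d_i-\hat d_j\|^2 + \lambda_{small}\sum_i\|\hat d_i\|^2\)
   over the whole stack (one sparse solve per component). Neighbourhoods
   are 8-nearest in-plane plus nearest-point links across consecutive
   interfaces. Edge weights use a Gaussian kernel at the median
   neighbour spacing and are degree-normalized, so the penalty acts as a
   first-difference seminorm: an isolated outlier is pulled roughly
   halfway to its neighbourhood mean at λ_smooth = 1 while a smooth
   large-scale field passes through nearly unattenuated. Defaults for
   `adjust_correspondences()` are λ_smooth = 1, λ_small = 0.1. Inside
   `reconstruct_brain()` the defaults are lighter (0.3 / 0.03) because a
   robust filter (drop matches deviating > 3 µm from the median
   displacement of their 8 nearest neighbours, and confidence < 0.7)
   runs first; with outliers removed, strong smoothing only biases the
   genuine deformation signal.
4. **Warping.** `mls_warp()`/`mls_transform()` implement
   similarity-variant moving least squares with weights
   \(w_i = 1/|v-p_i|^{2\alpha}\), α = 1, in complex form
   (\(M=\sum w\,\hat q\,\overline{\hat p} / \sum w|\hat p|^2\)), which
   reproduces any global similarity transform exactly — the variant that
   best matches the goal of warping slices with minimal shape
   distortion. Images are resampled by inverse mapping on a coarse
   evaluation grid.

`reconstruct_brain()` composes the four steps. To distribute the
measured inter-slice displacements along the stack without error
accumulation, the adjusted correspondences of each interface are
interpolated onto a regular node grid covering the correspondence hull
(local confidence-weighted linear fits — first-order, so smooth fields
keep their amplitude and gradient; no extrapolation beyond measured
support), and a small ridge-regularized chain least squares
\(\sum_s\|u_{s+1}-u_s+d_s\|^2+\mu\sum_s\|u_s\|^2\) (µ = 0.01) assigns
each slice its share of the correction. Per-slice warps are then applied
in-plane to every z-plane; `interface_mismatch()` scores the result
against the generator's recorded fields. On the default deformed-slice
phantom (1100 mixed-size somata in 240×240×120 µm, four 40-µm slices,
10 µm peak deformation, seed 0) the mean cross-interface mismatch drops
from ~7.6 µm to ~1.3 µm, a ≥ 5× reduction. Face images for matching are
the single plane adjacent to each cut: projecting deeper slabs mixes in
structure that exists on only one side of the cut and degrades matching
badly.

## Progressive HDR tone mapping

`bilateral_decompose()` splits log(1+I) into a base layer (bilateral
filter; spatial σ 6 px default) and a detail layer; the identity
base + detail = log(1+I) is exact by construction. The range sigma is
adaptive: 0.4 × (95th−5th percentile) of the log-gradient magnitudes,
recomputed from the current base at every compression step.
`progressive_compress()` applies n (default 3) global linear range
scalings about the current base midpoint, each multiplying the base
dynamic range by the factor (default 0.6); the global operator is our
choice — log-domain linear scaling is the simplest operator that is
monotone and leaves the detail layer untouched. `tonemap()` recombines
with the uncompressed detail, exponentiates and rescales affinely to
8 bits. Rescale anchors default per-image but can be imposed per-volume
so all planes of a brain share one mapping; monotonicity holds for the
global tone curve (ordered uniform inputs map to ordered outputs) —
pixelwise monotonicity across arbitrary image pairs is not a property of
any local base/detail operator and is not claimed.

## Cell detection

Detection is 2D-then-link, matching the anisotropic native sampling:

1. per plane, DoG maxima on the 4×-downsized image with
   σ1 = cell_size/(4√2) at the downsampled scale, σ2 = 2σ1 (the σ rule
   is our choice; only the DoG itself and the 4× downsizing are given),
   strict 8-neighbour maxima above a robust floor (median + 3·MAD of the
   DoG — a noise-floor definition that also suppresses weak texture);
2. per candidate, a patch of side 3 × cell size is thresholded at the
   mean of the peak value and the 1-px patch border ring ("edges of the
   patch" read as the perimeter), the connected component at the peak is
   kept, and patches containing several seeds are split by seeded
   gradient watershed (`EBImage::propagate`);
3. segments in adjacent planes are chain-linked greedily when centroid
   distance < cell_size/2 and area IoU > 0.2, ambiguity resolved by
   maximum IoU then minimum distance. Volume is Σ area × plane spacing;
   eccentricity is √(1 − λ_min/λ_max) of the intensity-weighted
   second-moment ellipsoid (note that at 3 µm plane spacing a true
   sphere measures ≈ 0.87 because sampling anisotropy enters the
   moments — validation ranges must be read in that light); records are
   validated against volume (100–4000 µm³), eccentricity (≤ 0.95) and
   intensity windows.

The detected count is invariant to a global intensity gain: both the
threshold formula and the MAD-based floor are gain-equivariant.
Colocalization is mutual-nearest-neighbour pairing within one cell
radius (5 µm default) — a deliberately conservative rule that cannot
double-assign. Atlas work is reduced to what the pipeline owns:
block-mean downscaling to 25 µm isotropic and applying an externally
supplied affine to cell coordinates; registration itself is delegated to
dedicated tools.

## Activation statistics

`relative_zscore()` standardizes each animal's regional count by the
control group's mean and sample SD (n−1; ddof is unstated in most
protocols, and the sample convention makes control columns exactly mean
0 / SD 1). `group_test()` runs per-region Welch t-tests ("unpaired
two-sample t-test" leaves the variance assumption open; unequal
variances is the safer default, and the generator's own truth has
group-dependent variances), Benjamini–Hochberg q-values across the 14
regions (with a Storey-π₀ option), fold changes and per-group CVs; a
degenerate zero-variance region falls back to an exact permutation
p-value. `simulate_cohort()` generates the 8 + 8 cohort over 14
subcortical regions (the named set includes PH and LHA to complete the
panel of stress-responsive areas): control counts ~N(800, (0.25·800)²)
truncated at 0; three regions (BMA, MEA, VMH) shifted by 3 control SDs
in the test group; most remaining regions given 2× test-group SD
(higher CV), and VMH given 0.5× (a ceiling-like variance reduction).
With that geometry the three shifted regions are detected at q < 0.05
with ≥ 90% power, and under the global null the fraction of q < 0.05
regions across 200 simulated cohorts stays ≤ 0.05.

## Numerical choices and degenerate inputs

* Trilinear/bilinear interpolation everywhere; outside-volume samples
  are zero-filled and flagged where they matter (truncated frames,
  clipped patches).
* Phase correlation clamps the cross-power modulus at 1e−12; NCC returns
  0 for zero-variance patches.
* MLS with coincident control points: consistent duplicates are merged,
  conflicting ones are an error; evaluation points striking a control
  point return its target exactly.
* Tone mapping of an all-zero image returns all zeros; rescale spans
  below 1e−6 (constant images) collapse to zero output rather than
  amplifying float noise.
* The adjustment solve is a symmetric positive-definite sparse system;
  non-finite solutions raise an error with no silent fallback.
* Problem sizes in the tests (phantoms ≤ 640×640×54 voxels, 200-cohort
  null simulations, 200-cell detection phantoms) were chosen so the full
  suite exercises every pipeline stage end-to-end on one CPU in a few
  minutes while keeping every statistical check at the stated power.

## Known limitations

* Stitching offsets are integer-voxel; no illumination flat-fielding or
  destriping; the two detection channels are assumed chromatically
  pre-aligned.
* The reconstruction aligns slices only where faces carry texture;
  regions outside the correspondence hull keep their nominal placement
  (constant extension of the node field). Sub-micron continuity of
  single axons across cuts is beyond the integer+MLS pipeline and out
  of scope.
* The detector assumes roughly convex somata/nuclei of a known scale;
  dendritic spines, axon tracing and learned segmentation are out of
  scope.
* Counts feed the statistics as absolute numbers per region; an optional
  per-volume normalization is trivial to apply upstream but whether
  published counts are density-normalized is often unstated — we use raw
  counts.
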