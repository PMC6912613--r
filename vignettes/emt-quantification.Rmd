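---
title: "Quantifying EMT-like phenotypes from live-cell imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMT-like phenotypes from live-cell imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtquant)
```

## Scope

When epithelial cells undergo an epithelial-to-mesenchymal transition
(EMT), the change shows up in live-cell imaging long before any molecular
assay: cells detach from their neighbours, move faster, form looser
aggregates, and invade 3D matrices as solitary cells. `emtquant`
implements the image- and table-based quantification pipeline for exactly
this phenotype panel: phase-contrast segmentation and confluency,
cluster-size distributions, collective motility by particle image
velocimetry (PIV), single-cell net-displacement statistics, spheroid
compactness, solitary-cluster invasion fractions, two-channel Pearson
co-localization, and relative gene expression by the 2^-ddCt method, with
a shared two-sample testing layer.

Microscopy data of this kind is rarely deposited, so the package also
ships a seeded synthetic-scene generator for every stage. Each generator
emits machine-readable ground truth, and the test suite validates every
estimator against closed forms, independent brute-force oracles, or that
ground truth.

## Conventions

All images are matrices in pixel coordinates `(row, col)`, 1-based as is
idiomatic in R, with the origin at the top-left; physical position is
`(index - 1) * pixel_size` µm. Spatial calibration (µm/pixel) and frame
intervals are always supplied by the user — they are never inferred from
image files, because standard TIFF/PNG exports do not carry reliable
calibration. Times are hours post-seeding.

## Segmentation by local brightness variability

Phase-contrast images of cells show strong local intensity fluctuation,
while cell-free substrate is optically quiet. `local_variability_map()`
computes the population variance in a `(2r+1)`-pixel square neighborhood
(default `r = 3`, a 7×7 window, matching the texture scale of cells at
10× magnification) using integral images, with reflected padding at the
frame edge. `segment_cells()` thresholds this map, applies a radius-1
morphological closing and hole filling to suppress speckle, and finally a
small compensation erosion (`edge_erode = 1`).

The compensation step deserves explanation. The variance kernel responds
as soon as any textured pixels enter the window, so the detected boundary
sits outside the true cell edge — at the default threshold, roughly half
a window radius. For a compact object of 400 px this outward bias alone
would cap the achievable intersection-over-union near 0.8; eroding by one
pixel re-centers the boundary. The parameter is exposed and can be set to
0 for raw thresholding.

The default threshold is Otsu's method on the log-variance map. Working
in log space makes the two phases (background variance vs. cell-texture
variance) symmetric and makes the threshold exactly invariant under
affine intensity rescaling. Otsu assumes both phases are present: if the
two classes it finds differ by less than `min_contrast_ratio` (default 3)
in variance, the map is effectively unimodal and the frame is reported as
uniformly covered, with a warning. This convention makes a fully
confluent culture score correctly, at the cost that a completely empty
*noisy* frame is ambiguous — within a single contrast-free frame there is
no absolute scale to tell "all cells" from "all background". Supply a
fixed `threshold` (e.g. calibrated on a known-empty field) when that
distinction matters. A strictly constant frame yields an empty mask.

On generator scenes with an object/background variance ratio of 10 the
segmentation reaches IoU ≥ 0.9 for objects of 400 px and larger; this is
what the tests demonstrate. Real phase-contrast data adds optical
artefacts (halos, shading, debris) that the i.i.d. Gaussian texture model
deliberately omits, so passing tests certify the estimator, not any
particular microscope.

## Cluster analysis

`label_clusters()` labels connected components of a mask — default
8-connectivity, since diagonally touching cell clusters are visually
contiguous — and reports physical areas, centroids, and a border flag.
Components below `min_area` (default 50 µm², sub-cellular debris) are
discarded but their total area is retained, so the conservation identity
*sum of cluster areas + discarded area = total mask area* holds exactly.

`size_histogram()` bins areas into half-open `[lo, hi)` bins with an
explicit overflow count, and `band_frequency()` reports the fraction of
clusters in a band, by default 300–3000 µm² — at typical epithelial cell
sizes, clusters of roughly 1–10 cells. A rising small-cluster band
frequency is the signature of impaired cell–cell adhesion. Because it is
not obvious whether such a comparison should pool clusters across
parallel fields or average per-field frequencies, both modes are
available (`pooled_distribution()` vs. per-field tables); pooled
frequencies equal the count-weighted mix of per-field frequencies, which
the tests verify as an algebraic identity.

## PIV motility

`piv_pair()` is classical window-based PIV: interrogation windows
(default 32 px with 16 px overlap) are matched by normalized
cross-correlation over integer shifts within `search_margin` (default
10 px, generous for cell displacements at 10-min intervals), followed by
parabolic sub-pixel interpolation of the peak along each axis. Only
windows with the full search margin inside the frame are evaluated — a
clipped search range cannot contain the true shift and would silently
bias the field.

Two gates flag unreliable windows. The peak must reach at least
`peak_min = 0.2`: on fully decorrelated noise the best of ~400 candidate
shifts only reaches a few hundredths for a 32-px window, while a genuine
match correlates near 1. And the peak must exceed the second-highest peak
(outside the 3×3 neighborhood of the first) by the ratio
`peak_ratio_min = 1.1`, rejecting ambiguous matches on periodic or
feature-poor texture. Identical frames are a special case: the
correlation peak is exactly 1 at zero shift and refinement is skipped, so
the reported displacement is exactly zero.

`frame_speed()` averages displacement magnitudes over valid windows and
converts to µm/h. By default `speed_timeseries()` restricts the average
to windows whose center lies on cell-covered pixels (mask from the
segmentation stage), since background windows are decorrelated noise that
would dilute the estimate, and truncates the analysis at `t_max = 100` h
(half-open, `[0, t_max)`) to avoid crowding effects in long recordings.
On generator movies the estimator recovers uniform translations of
0.5–8 px with a mean absolute error well below 0.2 px.

## Trajectory statistics

`net_displacements()` slides a window of fixed duration along a track
(stride in samples, default 1) and measures the straight-line distance
between the start position and the sample nearest to the window end,
accepted within half a sampling interval. `displacement_curve()` pools
windows across cells — matching the design of tracking a fixed number of
cells per condition — and reports mean and SEM per duration.

Overlapping windows maximize the information extracted from a small
number of manually tracked cells, but consecutive overlapping windows are
strongly correlated; a naive SEM over all windows would be overconfident.
The SEM denominator therefore uses the effective number of
*non-overlapping* windows, `sum(floor(span / duration))` over tracks. A
`per_cell = TRUE` mode averages within cells first and takes the SEM over
cells instead.

The estimator is validated against closed forms: ballistic tracks give
exactly linear curves; 2D Brownian tracks with diffusivity `D` have net
displacements that are Rayleigh with mean `sqrt(pi * D * duration)`
(recovered within 5% over a decade of durations with 200 simulated
tracks); persistent random walks (Ornstein–Uhlenbeck velocity) cross over
from ballistic scaling below the persistence time to diffusive scaling
above it.

## Spheroid compactness

Spheroid shape is scored by the normalized perimeter
`P / (2 * sqrt(pi * A))` — the perimeter relative to the equal-area
circle: 1 for a disk, `2/sqrt(pi)` ≈ 1.128 for a square, larger for
rougher outlines. Compact epithelial spheroids score near 1.3 in
practice; loose mesenchymal-like aggregates score much higher because
every attached protrusion adds perimeter at little area.

Measuring `P` on a raster is the delicate part: counting pixel edges
overestimates perimeters by up to a factor `4/pi` depending on
orientation, which would bias the ratio upward and unevenly. Instead,
`spheroid_metrics()` smooths the mask indicator with a Gaussian
(`smooth_sigma = 1.5` px) and measures the length of the 0.5 iso-contour
extracted by marching squares. The smoothing radius was chosen for
estimator accuracy on rasterized reference shapes: at σ = 1.5 the
residual pixelation ripple of the contour is suppressed while corners of
genuine features are barely rounded, giving a rasterized disk (r = 100
px) a ratio of 1.001, a square 1.122 (closed form 1.128), and a 2:1
ellipse within 0.2% of the elliptic-integral value. Smaller σ leaves
ripple that inflates perimeters ~1%; larger σ starts to erase real
protrusions. The area comes from the raw pixel count — smoothing affects
only the perimeter estimate.

`extract_spheroid()` segments the frame, keeps the largest connected
component and fills holes. Satellite clusters disconnected from the
aggregate are thereby excluded, while connected protrusions count toward
the perimeter — precisely the feature that separates loose from compact
aggregates.

## Invasion quantification

`split_central_solitary()` partitions a mask into the largest 8-connected
component (the central aggregate) and all other components of at least
`min_area` (the solitary clusters), with equal-size ties broken
deterministically toward raster order. The headline statistic is the
solitary fraction, solitary area over total cell-covered area, following
the convention of normalizing by the total area in the field rather than
the initial spheroid size. The central aggregate is re-identified per
frame rather than tracked from the first frame; for scenes where the
aggregate could shrink below a solitary cluster, per-frame bookkeeping
still flags rather than silently mis-scores, since empty segmentations
produce `NA` with a warning.

## Co-localization

`pearson_coloc()` is the plain pixel-wise Pearson correlation of two
channels — deliberately without Costes-style automatic thresholding,
which answers a different question. Correlation is computed within cell
ROIs rather than whole frames (`coloc_by_cell()`), because shared dark
background trivially inflates whole-frame correlations; the group summary
reports mean, SD, median and quartiles in box-plot convention. The
optional background subtraction removes the per-channel median and clips
negatives to zero; the clipping is what makes it matter, as subtraction
alone leaves Pearson's r unchanged.

## 2^-ddCt expression analysis

For each replicate, `ddct_fold_change()` forms
`dCt = Ct(gene) - Ct(reference)` within the replicate, then
`ddCt = dCt - mean(dCt_control)` and `fold = 2^-ddCt`. The reported fold
change is `2^-mean(ddCt)` — the geometric mean of per-replicate folds.
This choice makes the control sample score exactly 1 (an arithmetic mean
of per-replicate folds would exceed 1 for any centered scatter, by
Jensen's inequality) and respects the log-scale nature of Ct values. The
SD is reported over per-replicate folds, on the scale on which results
are read. Hypothesis tests run on dCt values, which are approximately
normal, never on folds. Because dCt subtracts the reference gene within
each replicate, a plate offset shifting all Cts of one sample cancels
exactly — the entire point of the normalization, and a generator-backed
test. Amplification-efficiency correction (Pfaffl) is out of scope.

## Statistics

`two_sample_test()` reproduces the common "F-test then t-test" protocol:
an F-test of variance equality at α = 0.05 gates between the
pooled-variance Student t-test and Welch's t-test. An F-test is sometimes
described as confirming normality; it does not — it compares variances —
and the gate is implemented as exactly that, with `always_welch` and
`always_pooled` available for forcing either branch.
`pointwise_significance()` applies the test independently at each time
point of two per-field series and flags p < 0.05 / p < 0.01, with no
multiple-testing correction across time points (the flags annotate a time
course; the returned metadata records this). The composite pipeline's
type-I error is verified by simulation to sit within [0.040, 0.060] at
nominal 0.05.

## The synthetic-data generators

The generators emulate the statistical structure each estimator relies
on, not microscope physics:

* **Culture scenes** — non-touching rectangles (pixel-exact areas) or
  disks filled with i.i.d. Gaussian texture on an i.i.d. Gaussian
  background; the variance ratio (default 10) is the single difficulty
  knob.
* **Translating movies** — a smooth periodic random texture (correlation
  length 1 px, the granularity of phase-contrast cell texture) shifted by
  exact sub-pixel amounts via bilinear interpolation with periodic
  boundary.
* **Tracks** — ballistic, Brownian, or persistent random walks (exact OU
  discretization), 25 h at 10-min sampling by default, mirroring typical
  manual-tracking sessions of 20 cells per condition.
* **Spheroid shapes** — star-convex polar boundaries (disk, square,
  ellipse, star, random Fourier), with truth area and perimeter taken
  from a dense polygon *before* rasterization.
* **Invasion sequences** — a fixed central disk plus square solitary
  blobs (default 20 px side, i.e. 400 µm² at 1 µm/px — the scale of a
  small multicellular cluster, and inside the segmentation's
  guaranteed-accuracy regime) appearing on a cumulative schedule; truth
  is measured from the generator's own masks, so mask-rendered scenes are
  recovered exactly by construction.
* **Co-localization pairs** — per-cell `B = rho * A + sqrt(1 - rho^2) *
  noise`, the exact population-correlation construction; 38 cells of
  2000 px by default.
* **Ct tables** — target genes shifted by `-log2(fold)` against the
  reference, Gaussian replicate noise (default SD 0.2 cycles, a typical
  qPCR replicate scatter), optional plate offsets.

All randomness flows through one seed per generator call
(`withr::with_seed`), so identical calls are bit-identical — itself a
tested contract. What these scenes do *not* contain: optical shading,
halo artefacts, cell divisions and deaths, out-of-focus drift, bleaching.
Tests passing on them certify the estimators' correctness and calibration
on data satisfying each method's stated assumptions, not performance on
any particular instrument's output.

## Problem sizes and numerical choices

The validation suite uses scene sizes chosen to exercise every code path
at comfortable desk scale: 128–320 px fields, 20 textures for PIV
recovery, 200 Brownian tracks, 38 co-localization cells, 10^4 null
simulations for test calibration. Key numerical conventions, collected in
one place: neighborhood variance is the population variance; padding is
symmetric reflection for filtering and edge-replication for erosion (so
full-frame masks are fixed points); morphology uses square structuring
elements; histogram bins and time windows are half-open `[lo, hi)`;
component ties break toward raster order; Otsu runs on 256 bins over the
data range (affine-invariant); PIV sub-pixel refinement is clamped to
±1 px and skipped at search-range borders and at exact-match peaks.

## Known limitations

* The variance-based segmentation cannot classify a contrast-free frame
  absolutely (see above); pipelines needing that must calibrate a fixed
  threshold.
* PIV measures the collective flow of texture, not single-cell
  velocities; strongly divergent motion within one window invalidates the
  window rather than resolving it.
* Automated cell tracking is out of scope: the trajectory module ingests
  externally produced tracks (CSV with `cell_id, t_h, x_um, y_um`).
* The normalized perimeter is resolution-stable only for objects ≳ 30 px
  across; below that the contour estimator's bias grows.
* 3D structures are quantified from their 2D projections, as in the
  underlying assays.
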