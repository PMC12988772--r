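---
title: "Multi-sample spatial omics with spatmosaic: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sample spatial omics with spatmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatmosaic)
```

## The problem

Imaging-based single-cell spatial omics platforms (multiplexed FISH, in
situ sequencing, spatial proteomics) produce, per tissue section, a
bundle of heterogeneous modalities: one or more microscopy images with a
physical pixel size, per-molecule transcript locations, one count matrix
per segmentation with per-cell tables and boundary polygons, sometimes
spot- or compartment-level measurements, and pathologist-drawn polygons.
Modern runs carry many sections or a tissue microarray (TMA) at once, so
analysis has to operate over a *cohort* of such bundles joined to
clinical or experimental metadata, not over a single matrix.

spatmosaic organizes this as a two-level hierarchy. A `spat_sample`
holds one section's data in six categories — `images`, `transcripts`,
`cells`, `units`, `annotations`, `regions` — and a `spat_experiment` is
an ordered list of samples joined row-by-row to a metadata tibble
through a unique identifier (UID). Annotations and regions are both
named, classed polygon sets but play different roles: annotations label
histology ("tumor", "stroma"), regions delineate structural units (TMA
cores, sections) and drive dataset splitting.

## Coordinate conventions

All stored coordinates are micrometres in one shared frame anchored to
the top-left corner of the primary fluorescence image; x runs rightward
along image columns and y downward along rows. The centre of pixel
(r, c) (1-based) sits at ((c − 0.5)·s, (r − 0.5)·s) for pixel size s.
Registration works in a second, pixel-valued frame (0-based, pixel
centres at integer coordinates) because transforms are estimated and
applied on pixels; conversion between the frames is a scale by the pixel
size.

Point-in-polygon membership is everywhere the even-odd rule with
boundary points counted inside — deterministic and checkable against a
half-plane oracle on convex polygons. Polygon rings are stored
implicitly closed (the first vertex is not repeated); writers emit the
explicit closure GeoJSON requires.

`crop_sample()` keeps a cell if and only if its centroid lies inside the
crop polygon; boundary polygons follow their cell and may protrude. The
alternative (clipping cells at the crop edge) changes matrix/boundary
cardinality mid-analysis and has no obviously right semantics for
counts, so the centroid rule was chosen and is stated rather than
inferred. Images are cropped to the polygon's pixel-aligned bounding
box; when several images with different pixel sizes are present, each is
cropped on its own grid, which can offset an image by less than one of
its pixels relative to the primary grid — negligible against
segmentation uncertainty, and exact in the common case of a shared
pixel size.

## On-disk projects: static versus variable data

A project directory separates *static* data — raw images and transcript
tables, which analysis never changes — from *variable* data — cell/unit
tables, annotations, regions, metadata, which it does. `saveas_project()`
writes both and records a SHA-256 digest of every static file in the
manifest; `save_project()` rewrites only the variable subtree, so
repeated saves of a large project cost seconds rather than the minutes
full image rewrites would take.

Opening a project is lazy for the heavy payloads: only the manifest and
the image sidecars are read; pixel and transcript payloads materialize
on first access. Large images are written as multi-page TIFFs whose
pages are fixed-size tiles with a JSON sidecar describing the grid, so
rectangular windows can be decoded without touching the rest of the
file. One consequence is deliberate: static digests are verified at
first payload access (and before `save_project()`), not at open —
verifying at open would force reading every payload byte and defeat
lazy loading. Corruption therefore still surfaces as an error, just at
first touch.

Image intensities are kept on their native scale (0–255 for 8-bit data)
as integer-valued doubles; the TIFF layer rescales to the format's
\[0, 1\] convention and restores integers exactly on read. Keeping
integers makes per-cell sums exact and independent of summation order,
which the tiling-invariance guarantee below relies on.

`to_flat()`/`from_flat()` provide a simplified flat export — keyed
element groups (`images`, `points`, `shapes`, `tables`) with
`<category>/<layer>` keys — for interoperability with flat,
keyword-addressed spatial frameworks. It is the package's own documented
layout, not a byte-level implementation of any external store, and is
lossless for directories it produced itself.

## Image registration

Post-run histology must be mapped into the fluorescence frame before
pathology annotations can meet omics data. The pipeline is the classic
feature-based one: grayscale/contrast preprocessing (with optional
intensity inversion so bright-field nuclei match fluorescence polarity,
and integer downscaling so the largest dimension is at most 4096 px),
scale-invariant keypoint detection and description in the SIFT
construction (difference-of-Gaussians octaves with 3 scales per octave
and base sigma 1.6, contrast threshold 0.0133, edge-response limit 10,
per-axis parabolic sub-pixel refinement, up to two orientations from a
smoothed 36-bin gradient histogram, 4×4×8 trilinearly binned descriptors
normalized–clipped at 0.2–renormalized), two-nearest-neighbour matching
under the Lowe ratio 0.75, and RANSAC (2000 iterations, 5 px
reprojection threshold on the downscaled frame) fitting an affine
transform by default — flat sections do not need the extra degrees of
freedom of a perspective fit, which is available on request. Matching is
exact nearest-neighbour rather than approximate: the contract (k = 2
plus ratio test) is identical and exactness only removes a source of
randomness; approximate search is a speed optimization that matters at
keypoint counts far beyond these images.

The result carries QC rather than a hard accept/reject: keypoint,
match and inlier counts, inlier fraction, mean reprojection error over
inliers, and the downscale factor. A result is *flagged* (not rejected)
when the inlier fraction falls below 0.2 or the inlier count below 8 —
an affine fits any three points, so a tiny consensus is not evidence of
alignment. On the package's synthetic nuclei images, planted similarity
transforms with rotation up to 20°, scale 0.8–1.25 and shifts up to 10%
of the image are recovered with mean corner error well under 2 px, and
self-registration is identical to machine precision; unrelated images
come back flagged or fail with stage-named errors.

## Tile-streamed quantification

`quantify_intensity()` computes per-cell statistics (mean, sum, max) of
an image channel while visiting the image strictly tile by tile:
per-cell running sums, pixel counts and maxima are merged across tiles,
so peak memory scales with the tile area plus the number of cells. A
pixel belongs to a cell when its centre falls inside the cell's
boundary polygon (cellular by default, nuclear by flag — platforms
differ in which is trustworthy), or, when a label mask is supplied, by
label equality, which takes precedence. The median is deliberately
unsupported: it is not mergeable across tiles, and offering it would
silently break the memory contract. Because intensities are
integer-valued, sums and maxima are bit-identical for every tile size,
and means agree to the division; the tests assert this against a
whole-image oracle.

## Multi-sample analyses

The built-in analyses are deliberately simple, documented defaults —
each is a tibble-in/tibble-out verb that can be swapped for a heavier
tool when a study needs one:

* **Composition** (`cell_composition`): per-group cell-type proportions;
  rows sum to 1, absent types are 0.
* **Density** (`cell_type_density`): centroid counts inside a polygon
  divided by its shoelace area, reported per mm².
* **Differential expression** (`differential_expression`): per-cell
  counts scaled to the median total of the pooled groups, two-sided
  Wilcoxon rank-sum per gene (normal approximation with tie
  correction, cross-checked in the tests against the reference
  implementation), log2 fold change on normalized means with a 1e-9
  pseudocount, Benjamini–Hochberg q-values over the tested set.
  Features missing from one side are dropped (intersection, with a
  warning) rather than zero-filled, to avoid fabricating measurements.
* **Pseudobulk** (`pseudobulk`): raw-count sums over member cells per
  group, conserving totals exactly.

## The synthetic generator as study conditions

`generate_sample()` is first-class, tested code, and its defaults are
the package's standard study conditions: 500 cells, 100 genes, 3 types,
a 1024 px image at 0.5 µm/px, marker fold change 4 with 10 markers per
type, type proportions (0.5, 0.3, 0.2) laid out as vertical bands (so
annotations and regions have non-trivial, verifiable contents), library
sizes lognormal(log 200, 0.3), transcript scatter sigma 3 µm, Gaussian
nuclear blobs over a smooth background texture with Poisson noise.
Construction identities hold exactly: the matrix total equals the summed
library sizes equals the transcript count, and every transcript carries
its emitting cell's id. `generate_experiment()` shares one base profile
across samples, assigns conditions round-robin, and plants two effects
in the treated condition: +0.15 on the type-1 fraction (the remainder
rescaled proportionally) and a 4× fold change on the last ten genes.
Its per-sample images default to 512 px — TMA-core-sized at 0.5 µm/px —
since a cohort of full-slide images would add nothing but time to
multi-sample logic. `generate_registration_pair()` renders a nuclei
image and produces the moving image by resampling through the planted
transform plus gamma 1.1 and Gaussian noise (sd 2/255).

What the generator does *not* emulate matters for interpreting green
tests: real tissue morphology (cells are jittered disks, not packed
epithelium), segmentation errors, optical blur/vignetting, batch
effects, or zero-inflation beyond multinomial sampling. Passing tests
certify the machinery — containers, I/O, geometry, streaming,
statistics — under known truth; they do not certify biological
conclusions on real data.

## Numerical choices and degenerate inputs

Round-trip fidelity targets are: count matrices exact (MTX text),
coordinates to 1e-6 µm (CSV/parquet at full double precision), polygon
vertex counts and classes exact. UIDs are random 128-bit hex strings
drawn from R's RNG so test harnesses can seed them. `query()` returns
views (samples are shared, not copied); `concat()` unions metadata
columns with explicit NA for absences and refuses UID collisions by
name. Degenerate inputs are contracts, not surprises: constant images
yield zero keypoints; crops with empty intersection yield valid empty
samples with a warning; cells covering no pixel get NA statistics with
a warning; polygons with fewer than three distinct vertices, zero-area
density polygons, out-of-range p-values, and UID mismatches on
`save_project()` are errors.

Problem sizes in the test-suite and acceptance script (e.g. 80-cell
192 px samples for tiling checks, ten 1024 px pairs for registration,
200 + 200 cells × 100 genes for DGE calibration) are the smallest at
which each property is meaningfully exercised at its stated tolerance;
they are the package's own choices and are stated where used.

## Known limitations

No 3-D (z-stack) coordinates; no nonrigid or mutual-information
registration (the affine/perspective model assumes flat, undeformed
sections); no vendor raw-bundle readers — the generic tabular importer
and the generator stand in; annotation GeoJSON follows the QuPath
classification dialect, other dialects import as "unclassified";
`query()`'s view semantics mean in-place edits to a queried sample are
visible through the parent experiment, which is intended but can
surprise; the flat export targets the package's own documented layout,
not byte-level compatibility with external zarr stores.
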