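---
title: "Quantifying astrocyte spatial organisation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte spatial organisation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrospat)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. It covers the measurement model, the synthetic
scenes used for validation, numerical conventions, and the places where a
design choice was genuinely open.

## The measurement chain

The package quantifies the spatial organisation of marker-positive
astrocytes in 2D fluorescence frames of striatal tissue. A frame passes
through these stages:

1. **Projection and segmentation.** Z-stacks are collapsed by per-pixel
   maximum (`max_project()`). A channel is thresholded at a fixed 8-bit gray
   level — 70 for astrocyte (GFAP) masks, 30 for aggregate puncta — and
   8-connected components become objects with intensity-weighted centroids,
   areas, and border flags (`segment_channel()`). Components smaller than
   `min_area_um2` (20 µm² for somata, 0.2 µm² for puncta by default) are
   treated as noise specks and dropped; both values are configurable and the
   cluster stage applies *no* minimum-area filter of its own.
2. **Counting and colocalization.** Per-frame counts include border cells
   and are normalised linearly to a reference area (0.4 mm² epifluorescence
   frames, 0.34 mm² confocal frames — always a parameter, never hard-coded).
   Dual-marker calls pair centroids across channels greedily in ascending
   distance, one-to-one, within 5 µm (about one soma radius), with
   lexicographic tie-breaks so the pairing is deterministic
   (`colocalize()`).
3. **Point-pattern statistics.** Each object set becomes a `point_pattern`
   in continuous physical coordinates. `nearest_neighbor_distances()`
   computes per-point NND with no edge correction by default — distances are
   measured on the raw frame, as they are in routine per-image analysis — and
   the spacing index is `mean(NND)² × density` with density = n / analysis
   window area (`spacing_stats()`). When a pattern is restricted to a named
   sub-region, the region polygon area is the density denominator.
4. **Cluster detection.** `detect_clusters()` implements the
   perimeter-distance definition: every object mask is dilated by a
   Euclidean disc of 10 µm, connected components of the dilated union are
   candidate clusters (so two objects join when their perimeters approach
   within 20 µm, and membership is transitive along chains), and components
   containing a single object are removed and logged as singletons.
5. **Compartmentalised puncta.** A punctum belongs to a compartment when its
   centroid pixel lies in the compartment mask; counts are conserved exactly
   and densities divide by the compartment areas (`count_puncta()`,
   `puncta_by_cluster()`, `wm_vs_gm_puncta()`).
6. **Regional quantification.** A user-supplied striatum outline is split
   into four quadrants at the midpoints of its bounding extent
   (`partition_striatum()`); fluorescence intensity is integrated density
   divided by region area (`region_intensity()`); fascicles are classified
   by cross-sectional area and associated with marker-positive cells via a
   10 µm halo (`classify_fascicles()`, `fascicle_marker_association()`).
7. **Statistics.** Image-level values are averaged to animals — the animal,
   never the image, is the unit of analysis — and groups are compared with
   the design-appropriate test (`aggregate_to_animal()`,
   `run_comparison()`).

## Why the spacing index

Mean NND falls when cells aggregate, but it also falls when cells simply
become more numerous. For a homogeneous Poisson process of intensity
$\lambda$, $E[\mathrm{NND}] = 1/(2\sqrt{\lambda})$, so
$E[\mathrm{NND}]^2 \lambda = 1/4$ independent of $\lambda$: the spacing
index removes the density confound. Clustered (Thomas) patterns score below
1/4; regular arrangements score above it (a square lattice gives exactly 1).
The package's calibration suite verifies all three regimes, and the
density-confound property directly: doubling CSR intensity changes mean NND
by $1/\sqrt{2}$ and leaves the spacing index unchanged.

Edge handling matters here. Per-frame NND with no correction is biased
upward (points near the border lack neighbors beyond it), which inflates the
spacing index above 1/4 — the control cohort in the worked example sits near
0.30. The package therefore also provides a toroidal evaluation mode, used
by the calibration tests to hit the analytic limit (0.25 ± 0.02 over 200
replicates); the default remains uncorrected because that is how per-image
values are produced in practice, and group contrasts compare like with like.

## The cluster criterion

The cluster rule is stated in micrometres (10 µm from each perimeter, 20 µm
total) and the implementation keeps it that way: the dilation radius is
converted to pixels at the image's own scale, because a literal fixed-pixel
enlargement would mean different physical distances on different microscopes
(`radius_px` exists for exact replication of fixed-pixel workflows). The
structuring element is an exact Euclidean disc, implemented by thresholding
the distance transform of the background, not a square kernel — the
criterion is an isotropic distance.

Two cluster-area conventions coexist in the field: the area of the merged,
dilated component (which includes the 10 µm margin, matching
enlarge-then-measure workflows) and the union of the undilated member
masks. The package reports both (`area_um2` and `core_area_um2`) so the
choice is explicit downstream.

`cluster_graph_oracle()` is an independent verifier kept deliberately
trivial: on scenes whose objects are exact discs it builds the
boundary-gap graph and returns its connected components. The pixel-based
detector is required to agree with it except when a gap falls within one
pixel of the 20 µm criterion, where rasterisation legitimately rounds
either way.

## Synthetic scenes: what they emulate and what they do not

`scene_spec()` / `simulate_scene()` generate the study conditions the
package is validated on:

- **Frame**: 632 × 632 µm (0.4 mm²) at 1 µm/px by default.
- **Somata**: homogeneous Poisson at 7.5 × 10⁻⁵ cells/µm² (≈30 per frame,
  a realistic marker-positive astrocyte density) for control-like scenes;
  a Thomas process (Poisson parents, Poisson(µ = 5) offspring per parent,
  isotropic Gaussian dispersion σ = 10 µm, matched to the 20 µm cluster
  scale) for disease-like scenes. Offspring falling outside the frame are
  discarded; a toroidal option exists solely so calibration tests can avoid
  edge bias.
- **Rendering**: each soma is an isotropic Gaussian blob (σ = 3 µm default;
  the cohort demo uses 1.5 µm to keep clustered somata resolvable) of peak
  amplitude 180 on background 10, plus optional Gaussian read noise,
  rounded and clipped to 0–255 on a *fixed* linear scale — never per-image
  rescaled, because fixed thresholds (70, 30) are only meaningful against a
  stable intensity scale.
- **Dual-marker status**: each cell is positive on the second channel with
  probability `coloc_fraction` (default 0.35, the typical share of
  GFAP-positive astrocytes also expressing S100B).
- **Puncta**: an inhomogeneous Poisson field, 10⁻³/µm² outside and
  10⁻⁴/µm² inside exclusion territory (cluster ground-truth zones and
  fascicle masks), generated by exact thinning.
- **Fascicles**: filled ellipses spanning the small/medium/large area
  classes.

All randomness flows from one explicit seed through a deterministic
sub-seed derivation; the same spec is bit-identical on every run, and no
global RNG state leaks (`.Random.seed` is saved and restored).

What the scenes do **not** model: astrocyte process arbors (blobs
approximate somata only, sufficient for centroid-based statistics but not
for morphology), true 3D structure, a realistic PSF, tissue
autofluorescence, or spatially varying background. Passing tests on these
scenes therefore validate the *operators* — counting, NND, clustering,
compartment densities — not the biological fidelity of any particular
segmentation on real tissue.

## Numerical conventions and degenerate inputs

- Pixel grid: origin top-left, pixel (r, c) has center
  ((c − 0.5) · ps, (r − 0.5) · ps) µm; areas are pixel counts × ps². All
  statistics run in continuous µm; rasterisation happens only at rendering
  and mask operations.
- NND search: exact grid-accelerated expanding-ring lookup whose cell sizes
  divide the window evenly, so the termination bound holds in both plain
  and toroidal metrics; it is required (and tested) to agree with an
  all-pairs scan bit-for-bit. Duplicate points yield distance 0 with a
  warning; fewer than two points is an error.
- Empty segmentations produce empty cluster sets with a warning;
  zero-area compartments with nonzero puncta flag the density as undefined
  rather than dividing by zero; degenerate (zero-area) striatum polygons
  are rejected.
- Polygon operations (shoelace areas, Sutherland–Hodgman clipping against
  the axis-aligned quadrant rectangles, point-in-polygon lookups) are exact
  to floating point; quadrant areas are tested to sum to the outline area.
- Boundary conventions declared once and tested: fascicle areas of exactly
  1,000 or 5,000 µm² are *medium*; threshold comparison is `>=`; quadrant
  naming depends on a per-image `medial = "left"|"right"` declaration
  because coronal sections can be mounted either way.

## Statistical layer

`choose_normality_test()` encodes the sample-size dispatch: n ≥ 8 →
D'Agostino–Pearson omnibus (implemented from the standard skewness and
kurtosis transformations, since no installed routine provides it, and
verified against an independent implementation's reference values), n < 8 →
Shapiro–Wilk, n < 3 → error. When normality fails, `run_comparison()` still
runs the parametric test and records the failure as a caveat — silently
switching tests would change the analysis mid-stream. Standard tests are
called from base R and emmeans (t, ANOVA, Tukey HSD, Sidak-adjusted
contrasts); the bespoke content is the dispatch, the image→animal→group
aggregation order, and the pairing structure (paired designs key strictly on
`animal_id` and are invariant to row order). Significance is a pure function
of p-value and α (default 0.05).

## Validation problem sizes

The shipped calibration suite uses: 100 random patterns (n ≤ 500) for NND
oracle equivalence; 200 replicates of 1000-point CSR patterns for the
spacing-index limit; 100 Thomas/CSR pairs (20 expected parents, µ = 5,
σ = 10 µm, density-matched CSR) for discrimination; 50 random disc scenes
at 0.5 µm/px for cluster-oracle agreement; 100 rendered scenes with nine
parents at 200 µm separation for planted-cluster recovery; 100 puncta
fields for conservation and ratio recovery; paired cohorts of 5 animals ×
3 images per genotype for the end-to-end demo; and 2000 null replicates for
the t-test's type-I rate. These sizes put Monte-Carlo error comfortably
inside each tolerance while keeping the full suite to a few minutes.

In the planted-cluster check, a planted cluster is a parent contributing at
least two *resolved* objects: when two somata are so close that their blobs
merge into a single segmented object, that object is a singleton by the
cluster definition (a cluster "contains more than one astrocyte"), so
scoring recovery against resolved objects — each assigned to its nearest
parent — isolates the clustering operator from segmentation merge effects.
The recovery scenes use offspring dispersion σ = 5 µm so that sibling
objects always sit well inside the 20 µm chain criterion, with parent
separation (200 µm) far beyond it.

## Known limitations

- Manual center-dot workflows are supported only through CSV import of
  externally placed centers; the automated surrogate (intensity-weighted
  centroids) differs from a human's nucleus-guided placement.
- No edge-corrected NND estimators (Hanisch, border correction) — per-frame
  raw distances are the deliberate convention, with toroidal mode for
  calibration only.
- The quadrant construction takes the striatum outline as given; anatomical
  landmark identification is manual and out of scope.
- No Ripley's K / pair-correlation alternatives in the headline path, no
  density-based clustering (DBSCAN and relatives), no machine-learned
  segmentation, no 3D analysis.
- ROI interchange is JSON polygons; binary ImageJ `.roi` files are not
  parsed.
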