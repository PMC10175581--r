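# astrospat

Spatial quantification of marker-positive astrocytes in 2D fluorescence
images of striatal tissue, with a synthetic-scene generator that provides
exact ground truth for every stage.

## The problem

Reactive astrocytes (GFAP⁺) in the diseased striatum do not merely become
more numerous — they rearrange, aggregating into "patches" near white-matter
fascicles and avoiding regions of high protein-aggregate load. Quantifying
that claim from immunofluorescence images takes a chain of measurements,
each simple but easy to get subtly wrong:

- **Counts**: marker-positive somata per standard frame (normalised per
  0.4 mm², border cells included).
- **Nearest-neighbor distance (NND)**: for each cell center, the Euclidean
  distance to its closest neighbor. Raw NND confounds aggregation with
  density, so the package also computes the **spacing index**,
  `NND² × density`, a dimensionless statistic that equals 1/4 in expectation
  for complete spatial randomness (CSR), falls below it for clustered
  arrangements, and is invariant to uniform density changes.
- **Cluster detection**: the perimeter-distance rule — two astrocytes belong
  to one cluster when their mask boundaries approach within 20 µm (each mask
  dilated by a 10 µm Euclidean disc; connected components of the dilated
  union; single-object components removed).
- **Compartmentalised puncta densities**: aggregate puncta (fixed threshold
  30) counted inside vs outside cluster footprints, and inside white-matter
  fascicles vs gray matter, each divided by its compartment area.
- **Regional quantification**: striatal quadrants (dm/dl/cm/cl) from
  midpoint splits of the outline's extent, area-normalised fluorescence
  intensity (integrated density / area), fascicle size classes
  (small < 1,000 µm², medium 1,000–5,000 µm², large > 5,000 µm²), and
  marker–fascicle association.
- **Statistics**: image values averaged to animals (the unit of analysis),
  normality checked with D'Agostino–Pearson (n ≥ 8) or Shapiro–Wilk (n < 8),
  groups compared by t-test / one-way ANOVA + Tukey / two-way ANOVA + Sidak.

Because studies of this kind rarely deposit raw images, the package ships a
generator of synthetic scenes with known ground truth — homogeneous Poisson
(control-like) and Thomas-clustered (disease-like) somata rendered as 8-bit
blob images on a fixed intensity scale, puncta fields with masked depletion
zones, elliptical fascicle masks — so every operator is validated against
exact geometry before it touches real data.

## Worked example

Simulate paired cohorts (5 animals per genotype, 3 images each: a CSR
control and a Thomas-clustered disease-like group at 1.5× intensity with
puncta depleted 10× inside cluster territory) and run the whole pipeline:

```r
library(astrospat)
demo <- run_demo_cohorts(seed = 1, n_animals = 5, n_images = 3)
demo$group_means$mean_nnd
#>       wt    zq175
#> 63.57316 14.78784
demo$group_means$spacing_index
#>      wt   zq175
#> 0.30150 0.02076
demo$group_means$cluster_area
#>        wt     zq175
#>  731.0056 1364.2280
demo$comparisons$spacing_index
#> t = 17.950, df = 8, p = 9.514e-08
```

Reading: the clustered cohort shows a lower mean NND (14.8 vs 63.6 µm) and
a spacing index far below both the control and the CSR reference of 0.25,
larger cluster footprints, and a ~10× depletion of puncta inside clusters
(`demo$group_means$puncta_in_density`: 5e-5 inside vs 9.5e-4 /µm² outside) — the
qualitative signature the pipeline is built to detect. The control cohort
sits near the CSR limit (spacing index 0.302; the excess over 0.25 is the
expected edge effect of uncorrected per-frame NND).

Individual stages compose with plain data frames and the pipe:

```r
scene <- simulate_scene(scene_spec(seed = 42, astro_process = "thomas",
                                   intensity_lambda = 2e-5))
seg   <- segment_channel(scene$channels$marker_a, threshold = 70,
                         min_area_um2 = 5, pixel_size_um = 1)
cl    <- detect_clusters(seg, dilation_radius_um = 10)
tidy(cl)            # one row per cluster: members, dilated + core area
glance(cl)          # one-row summary
puncta <- segment_channel(scene$channels$puncta, 30, 0.2, 1)
puncta_by_cluster(cl, puncta)
```

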