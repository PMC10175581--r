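Package: astrospat
Title: Spatial Quantification of Astrocyte Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial organisation of marker-positive
    astrocytes in two-dimensional fluorescence images of striatal tissue:
    threshold-based segmentation and per-frame cell counts, nearest-neighbor
    distances and the density-corrected spacing index, perimeter-distance
    clustering of GFAP-positive astrocytes by exact Euclidean dilation,
    compartmentalised puncta densities (inside versus outside clusters, white
    matter versus gray matter), striatal quadrant partitioning with
    area-normalised fluorescence intensity, white-matter fascicle size
    classification, dual-marker colocalization, and a statistics layer that
    aggregates images to animals and dispatches the appropriate tests. A
    synthetic-scene generator (homogeneous Poisson and Thomas point processes
    rendered as blob images, puncta fields with masked exclusion zones,
    elliptical fascicle masks) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    mgcv,
    emmeans,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
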