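Package: spatmosaic
Title: Hierarchical Multi-Sample Containers and Analysis for Single-Cell
    Spatial Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hierarchical framework for multi-sample, single-cell spatial
    omics data. Provides a per-section sample container with six data
    categories (images, transcripts, cells, spatial units, annotations,
    regions), an experiment container joining samples to a metadata table by
    unique identifier, an on-disk project format with static/variable save
    semantics and lazy image/transcript loading, automated feature-based
    registration of post-run histology images to the run's nuclear
    fluorescence image (scale-invariant keypoints, ratio-test matching,
    RANSAC affine or perspective fitting with quality-control metrics),
    tile-streamed per-cell immunofluorescence quantification, and built-in
    multi-sample analyses: cellular composition, cell-type density,
    differential expression and pseudobulk aggregation. A synthetic-data
    generator with known ground truth makes every component testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    digest,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
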