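Package: isletscape
Title: Whole-Slide Morphometry, Immune Burden and Spatial Statistics of
    Pancreatic Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A semi-automated analysis pipeline for whole-slide
    histopathology of the human pancreas across stages of type 1 diabetes.
    Builds islet objects from multiplexed hormone-stain geometry (stain
    merging, hole filling, size and tissue-border filters, shape
    descriptors), quantifies per-islet hormone staining areas, overlap
    statistics and deficiency phenotypes, constructs non-overlapping
    peri-islet regions to attribute CD45+ immune cells and score
    insulitis, embeds single-islet feature vectors with UMAP and clusters
    them with two-round DBSCAN, and computes boundary-aware spatial
    statistics (tissue-weighted Ripley's K, fractal dimension, Delaunay
    neighborhood metrics, class-specific isolation). A seeded synthetic
    cohort generator with full ground truth stands in for non-public
    whole-slide images and makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    deldir,
    uwot,
    sp,
    minpack.lm,
    jsonlite,
    yaml,
    digest,
    ggplot2,
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
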