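Package: thrombomap
Title: Multi-Parameter Analysis of Microfluidic Thrombus Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whole-blood thrombus formation from flow-chamber
    microscopy images and compares platelet phenotypes across mouse strains.
    Provides an FFT bandpass background correction and grayscale morphology
    pipeline for brightfield and fluorescence images, surface-area-coverage
    segmentation, assembly of the eight thrombus-formation parameters with
    per-experiment averaging and inclusion rules, univariate 0-10 scaling with
    wild-type subtraction heatmaps and a composite mean +/- SD relevance
    filter, Kendall tau-b correlation matrices, hierarchical clustering and
    phenotype concordance tables, a self-contained MCODE clustering of
    confidence-weighted protein-interaction networks, and seed-deterministic
    synthetic-data generators with exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    igraph,
    stats,
    tools,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
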