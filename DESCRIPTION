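Package: micropattern
Title: Quantitative Phenotyping of Micropatterned Stem-Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An image-to-phenotype analysis pipeline for micropatterned
    induced pluripotent stem cell (iPSC) germ-layer differentiation assays.
    Segments nuclei in the DAPI channel of multi-channel well images,
    groups them into colonies, applies morphology-based colony quality
    control (area, roundness, well-edge exclusion), computes radially
    binned marker-expression profiles (20 concentric 25-micrometre rings)
    with DAPI normalization, background subtraction and within-well max
    scaling, quantifies percent-positive cells per colony, calls
    phenotypic outlier lines (pooled two-tailed t test, Kolmogorov-Smirnov
    comparison against a control line), and filters annotated
    non-synonymous single-nucleotide variants by rarity and predicted
    deleteriousness. A seeded synthetic-data generator produces
    ground-truthed well images and variant tables so that every stage is
    testable without microscope or exome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
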