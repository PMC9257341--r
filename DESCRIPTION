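Package: imcmicroenv
Title: Single-Cell Segmentation, Phenotyping and Microenvironment Analysis
    for Imaging Mass Cytometry of the Decidua
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for in-situ single-cell analysis of
    multiplexed imaging mass cytometry (IMC) data of decidual tissue:
    DNA-driven nucleus segmentation with 2-pixel label expansion,
    binarized per-channel marker quantification as positive-pixel
    fractions, hierarchical phenotype gating with a minimum cluster-size
    rule, and a radius-based cell-cell microenvironment statistic with
    frequency-product expectation correction and permutation z-scores.
    Includes a marked point-process simulator that rasterizes
    ground-truthed IMC-like image stacks with controlled phenotype
    frequencies and planted spatial attraction or repulsion, so every
    stage of the pipeline is testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    pheatmap,
    stats,
    tiff,
    utils,
    grDevices,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
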