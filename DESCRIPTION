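Package: mmpscreen
Title: Plate-Based Mitochondrial Membrane Potential Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for JC-10 ratiometric mitochondrial membrane potential
    (MMP) high-throughput screens and their downstream validation assays.
    Provides plate-format data handling with wild-type-referenced
    normalization and duplicate-well aggregation, assay quality control
    (per-plate Z'-factor, duplicate coefficient of variation),
    distribution-aware hit calling via a from-scratch two-component Gaussian
    mixture EM fit with BIC-based modality assessment, per-cell F590/F520
    ratiometric image quantification, mitochondrial aspect-ratio and
    form-factor morphometry from binary masks, spontaneous calcium transient
    detection from fluorescence time series, and neurite morphology metrics
    (total dendritic length, terminal points, Sholl profiles) from SWC
    reconstructions. Includes seeded synthetic-data generators with full
    ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr,
    igraph,
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
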