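Package: pvniche
Title: Perivascular Immune Niche Quantification for Multiplex
    Immunofluorescence Cell Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial immune landscape of solid tumors from
    single-cell multiplex immunofluorescence data: boolean-marker phenotype
    gating (CD163+ macrophages, CD4+/CD8+ T cells, FOXP3+ regulatory T cells,
    checkpoint-regulator subsets), classification of every cell into
    perivascular (within 50 micrometers of a vessel boundary) versus
    non-perivascular areas of the tumor stroma and tumor cell islands,
    compartmental cell densities with region-of-interest to tumor to group
    aggregation, detection of three-cell perivascular contact clusters
    (macrophage + T cell + regulatory T cell), and group statistics
    (Mann-Whitney with Bonferroni correction, Pearson correlation, ROC/AUC).
    Includes a seeded synthetic tumor-map generator with known ground truth
    for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    mgcv,
    pROC,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
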