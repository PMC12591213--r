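Package: fibroscore
Title: Collagen Fiber Morphometry and Anchored ECM Turnover Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of collagen ultrastructure in
    picrosirius-red birefringence images. Provides a ground-truthed
    synthetic fiber-image generator for three extracellular-matrix states
    (homeostatic control, fibrotic deposition, age-like degradation),
    color deconvolution of mature and immature collagen stains in
    optical-density space, adaptive Wiener denoising, morphological fiber
    segmentation, skeleton-graph morphometry yielding 26 named
    ultrastructure parameters, an anchored LASSO-selected linear ECM
    turnover score calibrated so control maps to 0 and fibrosis to 1, a
    UMAP quality-control embedding, and hemisphere-geometry expansion-index
    kinetics with detection of the decoupling point that signals
    regenerative exhaustion during tissue expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    png,
    tiff,
    uwot,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
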