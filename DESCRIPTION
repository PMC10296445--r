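Package: spgdetect
Title: Spatially Predictive Gene Detection from Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies spatially predictive genes (SPGs) in spatial
    transcriptomic slides by training a dense feedforward neural network to
    predict each spot's (x, y) coordinates from its gene expression, then
    converting DeepLIFT feature attributions into per-gene importance
    statistics (CSMI, CSMNI, CSPNI) aggregated across slides. Includes the
    quality filters and normalization used upstream of training, 10-fold
    cross-validation with early stopping, cross-slide validation with center
    alignment, a seeded negative-binomial simulator of spatial expression
    with planted gene classes, and recovery benchmarking of the SPG call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
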