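Package: neuroquant
Title: Quantification Pipeline for Long-Term Neural Stem Cell Culture Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification computations for characterizing iPSC-derived
    neural stem cell cultures across long-term passaging: an integral
    squared-brightness immunofluorescence index with DAPI-channel
    normalization and negative-control comparison, minus-delta-delta-Ct
    relative qPCR expression with geNorm-style reference-gene stability
    ranking, single-cell RNA-seq quality-control filtering with cluster
    phase and lineage-composition summaries, and population-doubling
    curves for serial passaging. A synthetic-data module generates every
    input class with known ground truth so each stage is verifiable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
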