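Package: clustselect
Title: Characteristics-Based Selection and Evaluation of Clustering Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage workflow for choosing a clustering algorithm that fits
    a dataset and an analytical purpose, aimed at chemometric (FTIR/NIR/MIR
    spectroscopy) and omics applications. Stage 1 measures dataset and
    cluster-structure characteristics (size, dimensionality, balance, singleton
    clusters, density variation, elongation, outliers) from a labelled or
    provisionally clustered matrix. Stage 2 encodes the user's needs as a
    requirement profile. Stage 3 scores fourteen candidate clustering
    algorithms against the requirements using an encoded knowledge base of
    per-algorithm capabilities, parameter burden, determinism and time
    complexity, and down-selects a candidate subset. Stage 4 ranks the
    survivors quantitatively with the V-measure external validity index and
    internal indices (silhouette, Davies-Bouldin, Dunn) after
    spectroscopy-appropriate preprocessing (extended multiplicative signal
    correction) or standardization. Includes a synthetic-data module that
    generates labelled cluster structures and spectra with controllable
    characteristics so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
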