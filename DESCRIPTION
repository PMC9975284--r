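Package: MetSubtypes
Title: Pan-Cancer Expression Subtyping of Tumor Metastases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-study assembly and normalization of metastasis expression
    compendia, resampling-based consensus discovery of pan-cancer expression
    subtypes with minor-cluster reclassification, binary and signed
    nearest-centroid subtype classification, paired metastasis-versus-primary
    differential profiling, and downstream association statistics for copy
    number, somatic mutation, transcription-factor targets, reference
    signatures, and cell-line drug response. Includes a synthetic-compendium
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    fgsea,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
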