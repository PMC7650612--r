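Package: sigdyn
Title: Predicting Cell-Line-Specific Signaling Dynamics from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ordinary-differential-equation modeling of growth-factor
    signaling with initial protein amounts derived from RNA-seq expression
    (TPM) through trainable weighting factors. Provides joint parameter
    estimation across multiple cell lines with a real-coded genetic
    algorithm, ensemble-based prediction of untrained cell lines from their
    expression profiles alone, and initial-value sensitivity analysis of
    cumulative pathway responses. Ships a reduced ErbB receptor to ERK/Akt
    to c-Fos model together with a synthetic-data generator for end-to-end
    testing of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'expression.R'
    'model-core.R'
    'mini-erbb.R'
    'synthetic-data.R'
    'estimation.R'
    'sensitivity.R'
    'cli.R'
    'ga.R'
    'sigdyn-package.R'
    'utils.R'
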