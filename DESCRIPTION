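Package: cnasubtype
Title: Copy-Number-Based Discrimination of Lung Cancer Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature selection and classification pipeline for discriminating
    lung adenocarcinoma (ACA) from squamous cell carcinoma (SCC) using
    genome-wide SNP-array copy-number profiles. Implements minimum-redundancy
    maximum-relevance (mRMR) probe ranking on three-state discretized
    copy-number data, incremental feature selection driven by a cosine
    nearest-neighbour classifier under leave-one-out cross-validation,
    probe-to-gene interval mapping with symmetric upstream/downstream
    extension, and one-sided hypergeometric gene-set over-representation
    analysis. A synthetic cohort generator with planted, partially penetrant
    copy-number alterations and redundant probe blocks provides ground truth
    for validating every stage without array data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
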