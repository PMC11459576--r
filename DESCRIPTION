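Package: sclcpanel
Title: Targeted Expression-Panel Analysis and Transcription-Regulator
    Subtyping for Small Cell Lung Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of clinical targeted RNA expression panels of the
    NanoString hybridization-counting type, oriented at small cell lung
    cancer (SCLC) transcription-regulator subtyping. Implements
    negative-control background thresholding, positive-control scaling,
    geNorm reference-gene stability selection, housekeeping content
    normalization, and normalized log2 ratios against an in-batch
    universal reference sample; converts ratios into high-expression
    calls, dominant-regulator subtypes (ASCL1/NEUROD1/POU2F3/YAP1) and
    multi-marker profiles; quantifies agreement against orthogonal
    immunohistochemistry (PPA/NPA/PPV/NPV/OPA with Wilson intervals) and
    RNA-Seq; compares expression across histology cohorts; measures
    intra-patient multi-site heterogeneity; and simulates full synthetic
    cohorts with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
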