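Package: cpirex
Title: Kernel-Based Extraction of Compound-Protein Relations from Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level classification of candidate compound-protein
    pairs as functionally related or not, using two precomputed kernels: a
    shallow linguistic kernel (bag-of-n-grams over fore-between / between /
    between-after token patterns plus position-indexed local context
    features) and an all-paths graph kernel over weighted dependency graphs
    (label-allocation path-weight matrices compared by Frobenius inner
    product). Includes a support-vector classifier and a regularized
    least-squares classifier for precomputed Gram matrices, document-wise
    and nested cross-validation, a co-occurrence baseline, interaction-verb
    stratification with a chi-squared dependence test, conjunction of two
    kernel predictions with matched-precision threshold calibration,
    readers and writers for an annotated interaction-corpus XML dialect and
    the PubTator abstract format, and a seeded synthetic-corpus generator
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
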