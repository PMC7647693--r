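Package: lysucc
Title: Prediction of Lysine Succinylation Sites from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based identification of lysine succinylation sites.
    Extracts 31-mer windows centered on lysines, encodes them as amino acid
    composition (AAC), amino acid pair composition (AAPC) and the composition
    of k-spaced amino acid pairs (CKSAAP, k = 1..5), screens the 2000 CKSAAP
    attributes by minimum-redundancy maximum-relevance (mRMR) ranking followed
    by sequential forward selection, and trains a radial-basis-function
    support vector machine selected by cross-validated Matthews correlation
    coefficient. Includes position-specific two-sample enrichment statistics,
    a synthetic succinylome generator for end-to-end testing, and train /
    predict / evaluate entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
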