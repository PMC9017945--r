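Package: endopoe
Title: Parent-of-Origin Effects of RNA Pol IV on Endosperm Expression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting parent-of-origin effects of
    RNA polymerase IV on Arabidopsis endosperm. Quantifies small RNAs,
    mRNAs and DNA methylation in an allele-specific manner in triploid
    endosperm from reciprocal crosses using SNP pseudogenomes, calls
    24-nt siRNA clusters and sliding-window differentially methylated
    regions with dosage-aware filters, tests differential abundance with
    a negative-binomial engine using reference-feature size factors,
    classifies genomic imprinting, and detects antagonistic additive
    maternal/paternal effects on gene expression. Includes a synthetic
    endosperm data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
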