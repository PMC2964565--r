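Package: ldpanel
Title: Low-Density SNP Panel Design for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genomic prediction of breeding values and the design
    of low-density SNP genotyping panels in livestock. Implements SNP-BLUP
    ridge regression solved matrix-free with a preconditioned conjugate
    gradient on the mixed model equations, univariate partial least squares
    regression, cross-validated hyperparameter tuning (golden-section search
    for the ridge penalty), backward-elimination marker ranking, four
    low-density subset construction strategies (trait-specific top markers,
    evenly spaced markers chosen by index rank or minor allele frequency),
    and evaluation of direct genomic values against pedigree structure
    (tabular-method relationship matrix, sire-in-training grouping). A
    forward-in-time simulator of pedigreed populations with linkage
    disequilibrium provides fully reproducible test data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
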