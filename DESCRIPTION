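Package: wcadrift
Title: Within-Class Analysis of Transgenerational Transcriptome Drift
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing progressive transcriptional deregulation
    across generations in replicate mutant lineages. Implements
    median-of-ratios count normalization, log2 expression filtering,
    principal-component analysis on samples and on within-lineage expression
    differences, within-class (lineage-centered) PCA whose first-component
    gene loadings ("WCA scores") rank genes along a path to sterility,
    contributor-list selection with trajectory (priming and amplification)
    classification, and hypergeometric gene-set and chromosome enrichment
    statistics. A negative-binomial simulator generates count matrices with
    a 3-lineage, 4-state transgenerational design so the whole pipeline is
    testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
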