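Package: gsanova
Title: Gene and Gene-Set Mixed ANOVA for Paired Tumor-Normal Expression
    and Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mixed-model differential expression at the gene and gene-set
    (pathway) level for paired tumor-normal designs, with method-of-moments
    (Henderson Method III) variance components, Satterthwaite degrees of
    freedom, signed fold-change conventions with t-based confidence
    intervals, stratified replication with interaction tests, chi-square
    category enrichment scores, Venn-style intersection of differential
    pathway lists, and promoter-methylation delta-beta analysis of
    450K-style beta values.  Includes a synthetic-data generator that
    emulates the hierarchical person/sample random-effect structure the
    models assume, so every stage can be tested against planted truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
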