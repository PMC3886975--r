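Package: cnadriver
Title: Integrated Copy-Number, Expression, Methylation and Mutation
    Analysis for Subtype-Specific Driver Gene Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for nominating subtype-specific candidate oncogenes and
    tumor suppressor genes in tumor cohorts by integrating array-CGH copy
    number profiles, gene expression, promoter methylation and somatic
    mutation data.  Provides recursive binary segmentation of probe-level
    log2 ratios with categorical copy-number state calling, genome
    complexity classification (simplex / complex sawtooth / complex
    firestorm), subtype association screens with Benjamini-Hochberg false
    discovery control, a three-step copy-number-dosage / expression
    integration that classifies candidates as oncogenes or tumor
    suppressors, promoter methylation scoring with GC and quantile
    normalization and subtype-specificity calling, and mutual-exclusivity /
    co-occurrence testing of alteration pairs against a margin-preserving
    swap-randomization null.  A multi-omic cohort simulator with known
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
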