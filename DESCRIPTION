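Package: seqdirect
Title: Integrative Sequencing Cohort Analysis with a Contamination-Aware
    Tissue-of-Origin Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing integrative (DNA + RNA) tumor sequencing
    cohorts: an RNA expression tissue-of-origin classifier for cancers of
    unknown primary built as an equal-weight ensemble of nu-support-vector
    and multinomial-lasso models trained under three normal-tissue
    contamination schemes; a deterministic rule engine assigning genomic
    alterations to clinical-actionability tiers against a frozen local
    knowledge base; pathogenic germline variant categorisation with somatic
    second-hit detection; duration-based clinical-benefit and
    exceptional-response statistics; and a seeded synthetic-cohort generator
    so the whole pipeline is testable without access to controlled patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
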