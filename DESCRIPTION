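Package: iraesig
Title: Signal Detection and Novelty Filtration for Immune-Related
    Adverse Events in Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale pharmacovigilance toolkit for immune checkpoint
    inhibitor safety surveillance. Loads FAERS-dialect spontaneous report
    tables into a lightweight common-data-model case store (deduplication,
    drug-name-to-concept mapping, MedDRA event normalization), computes
    reporting odds ratio (ROR) disproportionality signals with Woolf 95%
    confidence intervals at the MedDRA preferred-term and system-organ-class
    levels, mines adverse-event terms from structured product label XML and
    literature abstracts by longest-match dictionary lookup against MedDRA
    surface forms, and partitions positive signals into labeled, unlabeled
    published, and potentially new categories. Includes evaluation metrics
    (precision/recall/F-measure, Cohen's kappa) and a synthetic-data
    generator that emulates every input format with injected associations of
    known odds ratio, so the whole pipeline is testable without licensed
    vocabularies or real report data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
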