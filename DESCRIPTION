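Package: pmcindex
Title: Policy Modeling Consistency (PMC) Index Evaluation of Policy Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for quantitative consistency evaluation of policy
    texts with the Policy Modeling Consistency (PMC) index: schema-driven
    binary coding of policies against a hierarchical indicator system,
    equal-weight primary-variable scoring, index aggregation and letter
    grading, 3x3 PMC-surface construction and rendering, corpus-level
    summaries and rank-group comparisons, and Pearson concordance between
    formulation-side index scores and implementation-side expert field
    scores. Ships the published scores of 37 county-level health promotion
    policies from the Sichuan pilot programme as a worked fixture, plus a
    seeded synthetic-data generator (Bernoulli indicator coding and a
    linear expert-score model) for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tibble,
    ggplot2,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
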