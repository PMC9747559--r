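Package: acmgconcord
Title: Concordance Analysis of Automated Versus Manual ACMG/AMP Variant
    Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating fully automated germline variant
    interpretation against high-confidence manual consensus calls in a
    carrier-screening setting.  Provides an ACMG/AMP evidence-combination
    engine (28 evidence codes, five-level classification, nonsense-mediated
    decay escape handling for PVS1, sub-population versus global allele
    frequency logic for BS1, majority-vote in silico consensus for PP3/BP4),
    a multi-submitter consensus builder that reproduces a high-confidence
    inclusion/exclusion funnel, per-variant and case-weighted confusion
    tables, a nine-category discordance classifier, and a seeded synthetic
    cohort generator so the entire pipeline is testable without access to
    proprietary clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
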