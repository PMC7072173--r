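Package: snohost
Title: Co-Alteration Analysis of Intronic snoRNAs and Their Host Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of copy-number and expression co-alteration of
    intronic small nucleolar RNAs (snoRNAs) and their host genes across
    tumor cohorts. Reads cBioPortal-style discrete copy-number (GISTIC
    codes) and RSEM-style expression matrices together with a snoRNA/host
    pairing table, classifies per-sample alteration events, computes
    cumulative alteration frequencies, cross-cohort recurrence categories,
    top-k recurrently altered couples, diploid-referenced expression
    Z-scores and up/down calls, exact 2x2 association tests, and ships a
    seeded multi-cohort synthetic data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
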