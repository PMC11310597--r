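Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous-Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for disproportionality analysis of FAERS-style
    spontaneous adverse event reports, built around the muscle-toxicity
    profile of colchicine, statins, and their combination. Reads quarterly
    ASCII tables (DEMO, DRUG, REAC, INDI, OUTC, THER), deduplicates cases,
    normalizes verbatim drug names to ingredients, assigns exposure groups
    from primary-suspect drugs, classifies myopathy cases with a
    narrow-scope standardised MedDRA query term set, and computes reporting
    odds ratios (ROR) and Bayesian information components (IC) with the
    conventional signal rule (at least 3 cases, lower ROR bound above 1,
    lower IC bound above 0). Includes a seeded synthetic FAERS generator
    with planted drug-event association strengths so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
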