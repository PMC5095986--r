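Package: mvldr
Title: Minimal Variant Level Data (MVLD) for Somatic Cancer Variant Curation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the Minimal Variant Level Data (MVLD) standard for
    clinical curation of somatic cancer variants: a typed record model with
    controlled vocabularies for every enumerated field, syntax-level HGVS
    validation of DNA and protein variant descriptions, a rule engine that
    checks records against the required/optional/conditional MVLD field
    logic, CanDL-style four-tier level-of-evidence assignment with six
    evidence sub-level categories, TSV/JSON serialization with round-trip
    guarantees, export toward ClinVar-style submission tables, cancer-type
    lookup against a packaged ontology subset, and a seeded generator of
    conformant and deliberately violating fixture corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
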