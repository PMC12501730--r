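Package: irdtriage
Title: Variant Triage, ACMG Classification and Diagnostic Yield for
    Inherited Retinal Dystrophy Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the desk work of molecular diagnosis in inherited
    retinal dystrophies (IRDs): an HGVS-lite parser for coding-DNA and
    protein change descriptions with consequence-type classification, an
    ACMG/AMP evidence-combination engine (strict rule-table and point-based
    modes), the step-wise triage cascade used on diagnostic panel output
    (variant fraction, population frequency, ClinVar assertion,
    consequence/splice filters) with a per-stage funnel report, per-patient
    case solving and cohort summary statistics (diagnostic yield,
    pathogenicity and variant-type distributions, gene recurrence, novelty
    reconciliation), trio segregation consistency checks, and a seeded
    synthetic-cohort generator with planted ground truth for end-to-end
    validation.  Ships a 94-patient IRD cohort's published variant and
    demographic tables as plain-text fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
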