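Package: thyrostage
Title: Anatomic Checklist Notation, Staging Rules and Understaging Audit
    for Grossly Invasive Thyroid Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for synoptic surgeon-pathologist reporting of grossly
    invasive thyroid cancer. Implements a machine-readable shorthand for
    anatomic structural involvement (laryngotracheal complex, bone, nerves,
    pharyngoesophagus, vessels and muscle, with degree-of-invasion
    superscripts and tracheal ring subscripts), a staging rule engine that
    derives AJCC 8th edition T-category floors and an ATA risk-of-recurrence
    tier from intraoperative findings, a cohort audit pipeline that detects
    understaged final pathology reports (including a from-first-principles
    two-tailed Fisher exact test), a packaged 35-case study cohort, and a
    seeded synthetic cohort generator for simulation and property testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
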