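Package: admpreg
Title: Antidiabetic Medication Utilisation in Pregnancy from Insurance Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs pregnancy episodes from health-insurance claims
    delivery codes (DRG and TARMED billing systems), imputes the last
    menstrual period and trimester windows, classifies antidiabetic
    medication (ATC A10) dispensation patterns into pregestational
    continuer/switcher, gestational-diabetes, and discontinuer groups, and
    estimates per-10,000 exposure prevalence with exact binomial confidence
    intervals by calendar year. Ships a seeded synthetic-claims generator
    with ground-truth labels that exercises every collapsing, relocation,
    and enrollment rule in the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
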