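Package: delphiScreen
Title: Delphi Consensus Statistics and Boundary-Value Indicator Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of multi-round Delphi expert consultations that build
    hierarchical indicator systems. Computes expert engagement (questionnaire
    recovery rate), authority (familiarity, judgment and authority
    coefficients), opinion concentration (mean importance, full-score
    frequency, coefficient of variation) and coordination (tie-corrected
    Kendall's W with chi-square test); screens indicators with the
    boundary-value method; tracks hierarchy evolution across rounds through
    an auditable edit log; and simulates expert panels with controllable
    consensus structure for validation. Ships a transcribed two-round
    reference consultation on a rat third-degree-burn model indicator system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
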