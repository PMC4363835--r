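Package: chronoherit
Title: Pedigree-Based Heritability of Diurnal Preference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for family-based studies of chronotype: scoring of the
    Horne-Ostberg Morningness-Eveningness Questionnaire (MEQ), pedigree
    validation and additive relationship (2*kinship) matrices, maximum
    likelihood estimation of the polygenic variance-components model
    (narrow-sense heritability with standard errors and boundary-corrected
    likelihood-ratio tests), summary-statistic effect sizes (Cohen's d with
    noncentral-t confidence intervals), and a gene-dropping simulator of
    multi-family cohorts for validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
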