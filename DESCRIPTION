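Package: sparscreen
Title: Early-Season Drought-Tolerance Screening of Crop Hybrids from
    Controlled-Environment (SPAR) Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for early-season drought-stress screening
    trials run in soil-plant-atmosphere-research (SPAR) chambers or similar
    controlled environments. From replicate-level phenotype observations (or
    a published trait-mean table) it computes treatment summaries and percent
    stress responses, individual and cumulative drought stress response
    indices (IDSRI/CDSRI), and an equal-width three-class tolerance
    classification of genotypes. A from-scratch inference layer provides
    two-factor randomized-complete-block ANOVA with star coding, Fisher's
    protected LSD mean separation with letter displays, and within-treatment
    Pearson correlation matrices. A synthetic trial generator with known cell
    means and configurable noise makes every stage testable without external
    data. Ships a built-in six-hybrid maize reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
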