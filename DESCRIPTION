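Package: srmsig
Title: Targeted SRM Quantification and Multi-Protein Response-Signature
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for stable-isotope-dilution selected reaction
    monitoring (SRM) data: turns transition-level peak areas into peptide
    and protein concentrations, qualifies each peptide assay from a
    dilution series (LOD/LLOQ under fresh-frozen or FFPE rule sets),
    imputes left-censored below-LLOQ peptide values, computes 5- and
    3-protein combined response-signature scores, and reports responder
    classification performance. Includes a seeded synthetic-data
    generator that emulates the measurement structure (triplicates,
    multiplicative noise, left-censoring, responder/non-responder effect
    sizes) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
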