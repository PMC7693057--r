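Package: msar
Title: Mean Species Abundance Relationships from Chronic Toxicity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives community-level mean species abundance relationships
    (MSARs) for chemical stressors from standard chronic toxicity tests.
    Species-specific survival and reproduction responses are fitted with
    two-parameter log-logistic models, converted to exposure-abundance
    curves through lifetime fecundity and logistic population-growth
    theory, and aggregated into an MSAR with Monte-Carlo uncertainty
    bands. Hazardous concentrations for 5% of species (HC5) are derived
    from both the MSAR and companion EC10-based species sensitivity
    distributions, together with variant MSARs that isolate the roles of
    endpoint choice and intraspecies exposure-response slopes. Includes a
    synthetic-panel generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
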