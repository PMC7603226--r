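Package: allerquant
Title: Targeted MRM Quantification of Milk and Egg Allergens in Baked Foods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for absolute quantification of milk and egg allergen
    contamination in processed (baked) food matrices from targeted multiple
    reaction monitoring (MRM) peak areas. Implements the peptide-to-total-
    protein unit conversion chain (peptide molarity, parent-protein molarity,
    relative abundance within the ingredient's total protein, extraction and
    clean-up volumetric factors), matrix-matched calibration with 3-sigma /
    10-sigma intercept-based limits of detection and quantification, censored
    concentration calls with qualifier-ion confirmation, in-house validation
    statistics (intra/inter-day precision with one-way ANOVA day comparison,
    recovery against reference materials, processing-effect sensitivity
    reduction), VITAL 3.0 action-level compliance decisions, and a seeded
    synthetic peak-area generator for end-to-end testing with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
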