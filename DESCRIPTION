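Package: fragsar
Title: Landscape-Scale Species-Area Relationships Under Late-Stage
    Habitat Fragmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fragmented landscapes by stratified random
    resampling of habitat patches (islands), computes landscape
    attributes (total area, patch number, patch size variability,
    landscape shape index, mean distance to mainland), fits the
    landscape-scale species-area relationship (LSAR) to derive
    z-values across patch numbers under observed and randomized
    (RDM/OWRDM) incidence data, locates z-versus-patch-number
    thresholds by two-segment piecewise regression, and attributes
    variation in z-values to habitat-area loss versus fragmentation
    per se by partial Spearman correlation and adjusted-R-squared
    variation partitioning. Includes a synthetic archipelago
    generator emulating a land-bridge island system so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, stats, utils
Suggests: testthat (>= 3.0.0), vegan, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
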