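Package: dualmap
Title: Dual Linkage and Association Mapping of Field Flowering Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for flowering-time phenology and genetics in
    inbred plant panels. Scales calendar flowering dates to photothermal units
    and chilling degrees from daily weather, fits the field-design linear model
    with least-square means and broad-sense heritability, runs genome-wide
    association scans by Wilcoxon rank-sum test and by a kinship-corrected
    mixed model, maps QTLs in recombinant inbred line families by Haley-Knott
    interval mapping with permutation thresholds, and combines both maps
    through candidate-gene window annotation, resampled enrichment null
    distributions and per-gene classification. Ships a seeded synthetic-data
    generator (structured accession panels, RIL families, weather and field
    layouts) so every stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
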