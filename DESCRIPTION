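Package: vinefert
Title: Nutrient Diagnosis and Precision Fertilization Modelling for
    Facility-Grown Grape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for multi-element fertilization trials on
    protected-culture grapevine. Computes a TOPSIS fruit quality index over
    single fruit weight, total soluble solids and firmness; analyses
    L16(4^5) orthogonal fertilization designs (range analysis, factor F
    values, LSD groupings, best-level combinations); derives compositional
    nutrient diagnosis cutoffs from cumulative variance-ratio functions via
    cubic inflection points and builds optimum nutrient ranges from
    high-quality reference sub-populations; accounts stage-wise whole-plant
    nutrient demand from destructive harvests; and implements a piecewise
    soil-test-based precision fertilization model with demand-ratio dose
    splitting and a non-negative least-squares fertilizer blend solver. A
    seeded synthetic-data generator emulates the 16-treatment, five-year
    experiment so the full pipeline runs end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
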