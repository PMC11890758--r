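Package: oncoscreen
Title: Screening Calculus for BRET Protein Interaction Mapping and
    Immune Co-Culture Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative scoring pipeline for live-cell BRET saturation
    assays and immune co-culture phenotypic screens. Fits hyperbolic BRET
    saturation curves, scores candidate protein-protein interactions by
    area-under-curve fold-of-change against dual empty-vector controls with
    Student's t-test hit calling, normalizes co-culture viability screens to
    percent-of-control, computes immune-killing selectivity indices, fits
    variable-slope (four-parameter logistic) dose-response curves, and
    provides the small downstream formulas used around such screens
    (comparative-Ct relative expression, differential-expression threshold
    filtering, caliper tumor-volume arithmetic). Includes seeded synthetic
    plate-data generators with known ground truth so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
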