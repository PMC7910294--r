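Package: screenfunnel
Title: Plate Normalization, Quality Statistics and Tiered Hit Calling for
    High-Content Inflammation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cell-based phenotypic compound screens read
    out by per-cell immunofluorescence. Provides long-format well-table I/O and
    layout validation, per-plate normalization to stimulated-vehicle controls,
    the Z-prime screening-window coefficient and control checks, a tiered hit
    funnel (effect size, replicate variability and cytotoxicity thresholds,
    dose selection and class-diversified ranking), four-parameter logistic
    dose-response fitting and inversion for stimulus calibration and
    immunoassay standard curves, quantification helpers for multiplex bead
    panels, antibody membrane arrays and delta-Ct expression ratios, and a
    seeded synthetic-screen generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
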