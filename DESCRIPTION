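Package: invadeloss
Title: Spatially Explicit Economic Loss Assessment for Invasive Alien Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An integrated raster pipeline for assessing the sectoral economic
    losses caused by invasive alien species. Heterogeneous infestation records
    (administrative presence-absence bulletins and presence-only occurrence
    points) are unified onto a single planar grid as a per-cell severity
    coefficient; district-level sectoral gross output is disaggregated onto the
    same grid with land-use allocation weights; spatial drivers are screened
    with the GeoDetector q-statistic and its interaction detector; losses are
    estimated with a staggered two-way fixed-effects difference-in-differences
    panel model and projected onto habitat-suitability surfaces to obtain
    potential-loss estimates with confidence intervals. A synthetic-scenario
    generator with known ground truth (landscape, staggered spread, occurrence
    points, economic panels) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
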