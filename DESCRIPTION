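Package: microdisp
Title: Dispersal Analysis for Two-Dimensional Fragmented Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for ciliate dispersal assays run in
    shallow two-dimensional patch-corridor microcosms. Provides the landscape
    geometry and zone assignment (Start / Corridor / Target / Control), a
    synthetic ground-truth generator emulating burst-mode darkfield imaging of
    Tetrahymena populations, particle detection and optimal frame-to-frame
    trajectory linking with quality filters, per-trajectory movement and
    morphology traits (swimming speed, path linearity, cell size and shape),
    landscape-level dispersal statistics (dispersal and emigration rates,
    termination and half-dispersal estimators, expansion front and rear,
    zone-wise distribution comparisons), and a decision-free correlated
    random-walk null model used as a baseline to infer dispersal decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    jsonlite,
    EBImage,
    tiff
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
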