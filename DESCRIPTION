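Package: landhab
Title: Land-Use Change Simulation and Habitat Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models land-use change and its consequences for habitat quality
    on categorical raster landscapes. Transition probability matrices are
    estimated by cross-tabulating two dated land-use maps and projected
    forward as a Markov chain; projected class areas are allocated in space
    by a constrained cellular-automata step that ranks cells on logistic
    land-suitability surfaces and neighbourhood density, under policy
    scenarios (fast urban growth, farmland conservation, ecological
    conservation). Habitat quality is scored per cell with a
    threat-degradation model combining distance-decayed threat kernels,
    class sensitivities and a half-saturation transform, with five-grade
    classification and grade-change accounting. A synthetic-landscape
    generator with known ground truth makes every stage testable without
    external data. Rasters are read and written as Esri ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
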