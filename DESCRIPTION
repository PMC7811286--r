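Package: nichespread
Title: Ecological Niche Model Calibration and Invasion Spread Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for estimating the climatically suitable area
    of an invasive species and simulating its spread on a grid. Provides
    occurrence cleaning and spatial thinning, predictor screening by
    correlation and PCA fitted on an accessible area and projected globally, a
    Maxent-style presence-background suitability model with an enumerated
    calibration grid, candidate evaluation by partial ROC, omission rates and
    AICc, threshold-based binarization and consensus mapping,
    mobility-oriented parity (MOP) extrapolation-risk trimming, a cellular
    automaton dispersal simulator on binary suitability with generalized
    Moore neighborhoods, and gridded presence-absence matrices with species
    richness summaries. Includes a seeded virtual-species generator so the
    whole pipeline can be exercised and validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
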