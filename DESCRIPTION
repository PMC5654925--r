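Package: canopymotion
Title: Nocturnal Canopy Movement Analysis from Terrestrial Laser Scanning Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Co-registers overnight time series of terrestrial laser scanning
    (TLS) point clouds against a fixed first scan using reference-sphere
    targets, extracts per-tree canopy height-percentile displacement series
    relative to the first-scan baseline, and classifies nocturnal crown
    movement into a four-type framework (sleep, drift, oscillation, noise)
    with an additive drift + circadian + short-period sinusoid decomposition.
    Includes a seeded synthetic scan simulator (parametric crowns, scanner
    ranging noise, ghost-point count fluctuation, per-scan rigid registration
    offsets, reference-sphere targets) so every pipeline stage can be
    verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
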