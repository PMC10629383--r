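Package: skystrip
Title: Dual-Platform Aerial Strip-Transect Survey Analysis
Version: 0.1.0
Authors@R:
    person("skystrip", "maintainers", email = "skystrip@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired human-observer and drone-imagery
    strip-transect surveys of marine megafauna. Implements pinhole
    georeferencing of tilted camera frames onto a planar sea surface,
    image-footprint overlap and dissolved-coverage accounting, chain-rule
    sighting deduplication and grouping, constant-visibility transect
    segmentation with environmental covariates, Huggins closed-capture
    estimation of perception bias with AICc model selection, Monte Carlo
    minimum-detections precision simulations, and Tweedie / zero-truncated
    Poisson count models comparing the two platforms. A synthetic-survey
    generator with known ground truth makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    mgcv,
    numDeriv,
    statmod,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
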