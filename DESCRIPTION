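Package: fnirsgraph
Title: Graph-Theoretic Analysis of Resting-State fNIRS Connectivity Across Cumulative Time Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for resting-state functional near-infrared
    spectroscopy (fNIRS) network analysis over the dorsolateral prefrontal
    cortex. Reads dual-wavelength raw-intensity recordings, repairs saturation
    dropouts, detects and corrects motion artifacts (spline relevelling plus
    wavelet coefficient thresholding), band-pass filters, converts optical
    density to chromophore concentration changes via the modified
    Beer-Lambert law, builds Pearson/Fisher-z functional-connectivity
    matrices over cumulative time windows, computes average degree and
    binarized-graph global efficiency across thresholds, and relates these
    graph metrics to behavioral scores with covariate-controlled partial
    correlations. Includes a synthetic-cohort generator with planted
    connectivity-behavior coupling so every stage is testable without
    access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
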