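Package: pmsensornet
Title: Calibration and Spatial Analysis for Low-Cost PM2.5 Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quality assurance and analysis of dense networks of
    low-cost optical particulate-matter (PM2.5) sensors deployed alongside
    regulatory monitors. Implements collocation-based per-sensor correction
    factors fitted against the network mean, precision and drift metrics
    (R-squared, RMSE, coefficient of variation, drift at fixed concentration
    levels), accuracy evaluation against beta-attenuation and gravimetric
    reference monitors including multi-linear meteorological bias regression,
    dew-point computation, pairwise spatial-variability statistics
    (coefficient of divergence, Pearson R-squared, Moran's I, distance decay),
    community group comparisons, and regression of concentration increments
    against a gridded emissions inventory. A synthetic campaign generator
    reproduces the statistical structure of a multi-month winter deployment
    (per-sensor linear biases, hygroscopic-growth humidity bias, nocturnal
    PM peaks, reference-monitor noise, missing data) so the full pipeline is
    testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
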