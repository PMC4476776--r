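Package: aiseffort
Title: Fishing-Effort Mapping from AIS Vessel-Position Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn raw AIS (Automatic Identification System)
    vessel-position messages into high-resolution maps of fishing effort.
    The pipeline links AIS-observed vessels to a fleet register by exact and
    fuzzy string matching, cleans per-vessel message sets, identifies fishing
    activity by fitting a two-component Gaussian mixture to each vessel's
    speed profile with an EM algorithm and classifying messages inside a
    +/- 1.5 SD band around the low-speed (towing) mode, validates the
    classification against logbook-derived kernel utilisation distributions,
    aggregates fishing time times engine power into kW-day effort grids at
    1x1 nautical mile, and estimates spatial AIS reception coverage from
    interpolated trajectories. A synthetic fleet simulator generates
    register, AIS and logbook tables with the statistical structure the
    pipeline assumes, so every step is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    geosphere
Suggests:
    mclust,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
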