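Package: flyway
Title: Annual-Cycle Analysis of Satellite-Tracked Migratory Shorebirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the annual cycle of long-distance
    migratory shorebirds from ARGOS satellite telemetry. Provides quality
    filtering of Doppler location classes, territory-centroid breakout
    detection of migration departures and arrivals with flight-speed
    event-time interpolation, continuous-time correlated random walk
    (integrated Ornstein-Uhlenbeck) fitting and smoothing to interpolate
    pathways across transmitter duty-cycle gaps, migration distance,
    duration and speed metrics, staging-area versus stopover classification
    with between-year site fidelity, and population-level phenology tables
    with two-tailed t-tests and Bonferroni correction. A synthetic-telemetry
    generator with ground-truth logs emulates two boreal-breeding whimbrel
    populations on the Western Atlantic Flyway so that every stage of the
    pipeline can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
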