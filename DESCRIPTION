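Package: intrunet
Title: Sex-Specific Neighbourhood Responses to Territorial Intrusions from
    Receiver-Grid Radio Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline from raw receiver-grid radio detections to
    sex-specific intrusion-response inference in territorial songbirds.
    Converts tag beacon logs (RSSI per receiver node) into half-minute
    position fixes by weighted-centroid plus nonlinear least-squares
    multilateration, computes neighbourhood outcome variables around a
    simulated territory intrusion (pre/post minimum approach distances of
    the closest male and female, 10-m proximity-network associate counts
    and association times), scores the territory owner's playback response
    by varimax-rotated principal components with KMO and Bartlett
    diagnostics, and fits sex-by-signal linear mixed models with
    likelihood-ratio interaction tests, per-sex post hoc contrasts and
    group-deletion influence checks. Includes a synthetic world generator
    (triangular receiver grid, Ornstein-Uhlenbeck territory-anchored
    movement, log-distance path-loss radio model, structured playback
    response tables) so the full chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
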