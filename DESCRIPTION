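Package: windfleckr
Title: Windfleck Detection and Wind-Driven Canopy Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying how wind-driven canopy motion creates rapid
    within-canopy light fluctuations (windflecks) in field crops. Implements
    frame-differencing motion quantification (quantity of motion, QOM) over a
    zone grid with static reference-zone correction, turning-point detection of
    windfleck events in high-frequency photosynthetic photon flux density
    (PPFD) series with dual amplitude thresholds, multi-rate time-series
    synchronization by cross-correlation, biomechanical trait formulas
    (natural frequency, leaf mass per area, height-to-mass and leaf-to-stem
    mass ratios), class-conditional windfleck frequencies, broad-sense
    heritability from variance components, and a seeded synthetic-data
    generator emulating wind, motion, irradiance, video frames, and trait
    tables so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mgcv,
    png,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
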