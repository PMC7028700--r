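Package: soyflood
Title: Process-Based Simulation of Waterlogging Stress in Soybean
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, daily time-step soybean cropping-system simulator
    focused on excess-water ("oxygen deficit") stress. Implements
    stage-dependent piecewise-linear stress multipliers on radiation-use
    efficiency, phenological development, and symbiotic nitrogen fixation,
    alongside the classical supply/demand drought stress, over a layered
    tipping-bucket soil water balance with perched water-table tracking.
    Includes a stochastic weather generator, a flooding-experiment scheduler,
    climate-change rainfall scenarios, a parameter sensitivity driver,
    goodness-of-fit metrics, and synthetic soil, cultivar and weather fixtures
    so that flood timing and duration responses and rainfall-scenario yield
    penalties can be simulated and analysed entirely offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
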