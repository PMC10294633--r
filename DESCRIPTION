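Package: bdellosim
Title: Predator-Prey Infection Dynamics and Cell-Cycle Statistics for
    Bdellovibrio bacteriovorus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the prey-size-dependent life cycle of the
    predatory bacterium Bdellovibrio bacteriovorus.  Provides a deterministic
    discrete-time predator-prey infection simulator with complete-lysis-time
    computation, a four-parameter Weibull kill-curve model with effective kill
    time (EKT50) estimation, summary statistics for single-cell cell-cycle
    event timings (replisome, segrosome and divisome appearance), and seeded
    synthetic-data generators that emulate single-cell event tables, paired
    prey-length/bdelloplast-diameter measurements and Bioscreen-style OD600
    kill curves, so every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
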