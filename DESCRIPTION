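Package: rhythmostat
Title: Circadian-Modulated Two-Process Simulation of Sleep-Wake Timing and
    Social Jet Lag
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates human sleep-wake timing with a circadian-modulated
    two-process ("rhythmostat") model in which homeostatic sleep pressure,
    expressed in relative slow-wave-activity units, builds up exponentially
    during wake and decays during sleep, with asymptotes, switching
    thresholds and time constants all modulated by a sinusoidal circadian
    term.  Provides an event solver for the threshold switches, steady-state
    free-running cycles, weekly schedule simulation with alarm-forced
    weekday risetimes, inverse calibration of the wake-phase time constant,
    age-group parameter sets, aggregation of sample-level sleep-time tables
    with confidence intervals, empirical-versus-simulated discrepancy tables,
    social-jet-lag shift metrics, and a seeded synthetic cohort generator
    emulating literature survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
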