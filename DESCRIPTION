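Package: pinchloop
Title: Simulation and Feature Extraction for Pinched Hysteresis Loops of
    Parallel Memristor-Capacitor Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the voltage-current behaviour of two memristor models
    driven by a sinusoidal voltage source - a self-heating NTC-thermistor
    model with a tangential pinched hysteresis loop and a modified HP
    linear-drift model with a transversal loop - alone, in parallel with
    each other, and in parallel with a constant capacitance.  Provides an
    adaptive Runge-Kutta-Fehlberg 4(5) simulation engine, a quantitative
    feature extractor for pinched hysteresis loops (pinch-point detection
    and classification, loop orientation, per-quadrant lobe areas, origin
    symmetry, memductance extrema, current peak lag, per-period state drift,
    phase-angle ranges), a registry of named reproducible simulation
    scenarios, and a generator of noisy synthetic recordings with known
    ground truth for testing loop classification, motivated by nonlinear
    bioimpedance measurements on human skin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
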