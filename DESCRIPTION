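Package: csoscillator
Title: CS-Oscillator Model of the Human Circadian Pacemaker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the human circadian pacemaker as a van der Pol-type
    limit-cycle oscillator (Process P) driven by a dynamic light-stimulus
    processor (Process L), with the circadian stimulus (CS) transform of
    circadian light (CL_A) as the photic input. Provides phase-marker
    extraction (minimum core body temperature, dim light melatonin onset),
    per-subject prediction of light-induced DLMO shifts from wearable
    light-logger time series, cohort accuracy metrics (MAE, percent of
    subjects within 1 h, R-squared), initial-phase and model-parameter
    sweeps, light-window masking, phase response curve simulation, and a
    synthetic Daysimeter-like cohort generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
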