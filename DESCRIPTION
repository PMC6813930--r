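Package: sepsim
Title: Whole-Body Simulation of Sepsis Progression and Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the progression of bacterial infection to sepsis and
    septic shock in a virtual patient, and the response to treatment. Couples
    an 18-state acute inflammatory response (AIR) ordinary differential
    equation model with a hysteretic toll-like-receptor switch to a reduced
    lumped-parameter physiology (Starling capillary fluid exchange, Patlak
    albumin transport, baroreflex hemodynamics, renal output, lactate and
    SIRS symptoms) and a treatment layer (two-compartment antibiotic
    pharmacokinetics with MIC-anchored pharmacodynamics, vasopressor
    infusion, crystalloid and colloid fluids). Provides outcome
    classification, critical-inoculum bisection, bistability scans, scenario
    scripting and the REFRESH fluid-resuscitation protocols.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
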