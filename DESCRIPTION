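Package: optoclamp
Title: Optogenetic Current Clamp Analysis of Cardiac Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for optogenetic current-clamp
    experiments in cardiac tissue. Couples a four-state channelrhodopsin-2
    (ChR2) photocycle model, calibrated against patch-clamp photocurrents,
    to a murine ventricular cardiomyocyte ionic model with a tunable
    inward-rectifier (I_K1) rectification exponent, a cation background
    leak, current-scaling modifiers and multichannel drug block. Provides
    in-silico protocols measuring resting membrane potential, input
    resistance (R_m) via subthreshold light pulses, and optical pacing
    thresholds (I_thr); an analysis pipeline for sharp-microelectrode
    membrane-potential recordings (cycle averaging, subthreshold
    depolarization, action-potential phases, delayed afterdepolarization
    detection, Ohm's-law input resistance); a convolution-based estimator
    of the electrotonic space constant from illumination-size series; and
    seeded synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
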