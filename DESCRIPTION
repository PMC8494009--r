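Package: phasedefect
Title: Phase Defect Analysis of Cardiac Excitation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing re-entrant activation patterns in cardiac
    tissue through the phase-defect framework. Computes activation phase,
    Hilbert phase and an arrival-time phase built from local activation time
    (LAT) maps; detects phase singularities (ring methods), conduction block
    lines from LAT jumps, and phase defect lines and surfaces from wrapped
    phase jumps; links detections over time into tracks and families and
    reports lifetime and co-location statistics. Ships a monodomain
    reaction-diffusion simulator (Aliev-Panfilov, Fenton-Karma and
    Bueno-Orovio-Cherry-Fenton kinetics) used to generate rotor, conduction
    block and scroll-wave test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
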