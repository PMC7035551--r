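Package: patbp
Title: Pulse-Arrival-Time Based Blood Pressure Estimation Models and
    Point-to-Point-Pairing Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cuff-less blood pressure estimation from pulse
    arrival time (PAT). Implements five BP-PAT models (MK-EE, L-MK,
    MK-BH, dMK-BH, M-M) spanning the vascular-elasticity and
    elastic-tube families, exact point-to-point-pairing (PTP)
    calibration with subset averaging over repeated calibration rounds,
    ECG/PPG beat delineation (R-peak to maximum PPG upslope), windowed
    PAT averaging, error metrics with AAMI compliance verdicts,
    Kruskal-Wallis/Dunn model comparisons, and a gamma-sensitivity
    sweep for the dMK-BH model. Includes a self-consistent synthetic
    cohort generator (post-exercise BP recovery, 1 kHz waveform
    rendering, noisy cuff readings) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
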