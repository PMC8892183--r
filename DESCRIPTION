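Package: tiltsim
Title: Closed-Loop Multiscale Hemodynamics Under Gravity and Head-Up Tilt
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A closed-loop, multiscale (1D-0D) simulator of the human
    cardiovascular system under gravity and passive posture change.
    Large systemic arteries are resolved as one-dimensional elastic
    vessels with a viscoelastic tube law and an axial gravity source;
    the microcirculation, venous return, venae cavae and the
    cardio-pulmonary circulation are lumped Windkessel compartments
    organized into five body regions, closed through a four-chamber
    time-varying-elastance heart, cardiac and venous valves, and a
    three-layer coronary microcirculation. Short-term regulation
    includes the arterial baroreflex, the cardiopulmonary reflex,
    cerebral autoregulation and an intracranial-pressure model.
    Head-up tilt and tilt-down protocols with configurable angle and
    rate reproduce steady-state and transient orthostatic responses
    (stroke volume, cardiac output, heart rate, central venous
    pressure, regional blood-volume shifts, stroke work, tension-time
    index and pressure waveforms along the arterial tree).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
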