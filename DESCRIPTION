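Package: oscreset
Title: Phase-Reset Analysis and Simulation of Spiking and Oscillating
    Electroreceptors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signal-analysis and behavioral-quantification tools for
    electroreceptor recordings in mormyrid weakly electric fish, together
    with a synthetic-data module so every analysis stage can be exercised
    without recorded data. Implements circular statistics (vector strength,
    circular correlation, the paired second-order Hotelling test),
    characterization of spontaneous 1-3 kHz receptor oscillations,
    Hilbert-phase independence tests between simultaneously recorded
    receptors, quantification of stimulus-evoked phase resets and
    oscillation amplitudes, frequency-tuning curves for spiking and
    oscillating receptors, interpulse-interval statistics of electric organ
    discharge trains, and spike-density-function metrics for behavioral
    playback experiments. The simulators cover forced Stuart-Landau
    oscillating receptors, edge-triggered spiking receptors with refractory
    periods, stimulus artifacts, and single-fish and group discharge trains.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
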