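Package: icephys
Title: Intrinsic Excitability Analysis for Current-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature extraction and group comparison for somatic
    current-clamp recordings from cortical pyramidal neurons: passive
    properties (resting potential, input resistance, sag ratio and
    H-current classification), single action-potential waveform features
    (threshold at the 20 V/s criterion, half-width, medium
    afterhyperpolarization, dV/dt extrema), spike-train accommodation,
    and decomposition of the action-potential rising phase into axon
    initial segment and somatodendritic components from the second
    derivative of the voltage waveform.  Includes a two-compartment
    conductance-based simulator that generates current-clamp sweep sets
    with known ground truth, scoring functions for common behavioural
    assays (prepulse inhibition, radial-arm-maze working memory,
    open-field jumping), and a normality-routed two-group statistical
    report generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
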