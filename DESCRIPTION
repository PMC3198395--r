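Package: gliarhythm
Title: Cycle-Triggered Analysis of Astrocyte-Neuron Coupling in Rhythmic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification pipeline for functional coupling between
    astrocytes and rhythmically bursting neuronal networks, as studied in
    the pre-Botzinger complex of brainstem slices. Implements burst
    detection on integrated field potentials, cycle-triggered averaging of
    whole-cell astrocytic currents and of calcium-imaging stacks,
    rhythmic-current (I_resp,A) amplitude quantification, input-resistance
    and current-voltage analysis, rolling-ball background subtraction,
    ROI delta-F/F0 traces, pixel-wise cross-correlation activity maps, and
    rhythmicity classification. Ships a seeded synthetic-data generator
    grounded in a passive-membrane potassium (Nernst) shift plus glutamate
    transporter current model of the astrocytic response, so every analysis
    stage is testable against ground truth without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
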