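Package: ca1ephys
Title: Feature Extraction and Group Statistics for Hippocampal CA1
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for slice electrophysiology of hippocampal
    CA1: extraction of intrinsic membrane properties (resting potential,
    input resistance, voltage-sag index, rheobase, spike threshold and
    amplitude, current-spike curves) from current-clamp step families;
    detection and quantification of spontaneous excitatory postsynaptic
    currents (amplitude, charge transfer, frequency) in voltage-clamp
    traces; evoked field-potential measurements (fEPSP initial slope,
    population-spike amplitude, stimulation thresholds, theta-burst LTP
    time courses); and the group-comparison statistics used for such data
    (one-way ANOVA with Levene's homogeneity test and Tukey's post hoc
    test, mean +/- SEM tables with significance stars). Includes a
    ground-truth synthetic-recording generator in two modes - exact
    parametric waveform construction and a mechanistic
    exponential-integrate-and-fire neuron with an h-current - for
    benchmarking every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
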