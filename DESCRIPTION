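Package: okndecode
Title: No-Report Binocular Rivalry Analysis: OKN Segmentation, Unit
    Selectivity and Population Decoding of Perceptual Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing extracellular recordings collected during
    no-report binocular rivalry experiments, in which the perceived motion
    direction is inferred from the optokinetic nystagmus (OKN) rather than
    from volitional reports.  The package covers spike detection from
    broadband voltage, automated segmentation of perceptual dominance
    epochs from eye traces, gamma statistics of dominance durations,
    rank-sum and d-prime unit selectivity, population and ensemble
    peri-switch time histograms, and single-trial population decoding with
    a maximum-correlation-coefficient classifier, including cross-temporal,
    cross-condition and cross-session generalization and permutation-test
    significance.  A synthetic-session generator reproduces the statistical
    structure these analyses assume (gamma-distributed dominance durations,
    percept-locked OKN with realistic switch latency, heterogeneous unit
    selectivity, feedforward transients at exogenous switches) so that the
    full pipeline is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
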