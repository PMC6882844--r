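Package: nanonmr
Title: Frequency Discrimination and Resolution for NV-Center Nano-NMR Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and classification toolkit for binary measurement
    traces produced by nitrogen-vacancy (NV) center magnetometers in
    nanoscale nuclear magnetic resonance (nano-NMR) experiments. Generates
    Bernoulli readout traces under a Ramsey-type phase-accumulation model
    with configurable phase-jump, magnetic-offset and amplitude noise, a
    two-efficiency photon-detection model, and Ornstein-Uhlenbeck modulated
    multi-component signals. Implements three competing classifiers for
    frequency discrimination (which of two known frequencies generated a
    trace) and frequency resolution (one central frequency versus two close
    frequencies): a full-Bayesian likelihood-ratio test maximized over
    nuisance phases or sampled Ornstein-Uhlenbeck realizations, a
    correlation-template nearest-class classifier, and a small feed-forward
    neural network. Includes balanced-error and ROC/AUC scoring plus sweep
    harnesses over frequency separations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
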