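Package: habgain
Title: Bayesian Information-Gain Model of Habituation to Novelty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models habituation to novel stimuli as the decay of information
    gain (Kullback-Leibler divergence from prior to posterior) under repeated
    Bayesian belief updates with a learning rate, in the conjugate Gaussian
    setting. Provides closed-form per-exposure gain, its continuous-exposure
    antiderivative and asymptotic total, the uncertainty-ordering reversal
    condition, and parameter-sweep tables of the decay curves. Also ships a
    generative emulation of a surprise/ERP habituation experiment (2x2
    familiarity-by-congruency design, Likert surprise probes, synthetic
    single-channel EEG epochs with a habituating P300-like component), the
    matching ERP analysis chain (zero-phase band-pass, baseline correction,
    amplitude-threshold artifact rejection, exposure-block averaging, P300
    peak measurement), and least-squares recovery of model parameters from
    observed decay curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
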