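Package: iedlfp
Title: Set-Shifting Task Simulation and Decoding of Outcome Valence from
    Intracranial Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bilateral local field potential (LFP)
    recordings acquired during an intra-/extradimensional (IED) set-shifting
    task. Provides a behavioural simulator of the nine-rule IED schedule and a
    matching LFP generator (1/f background, line contamination, condition- and
    hemisphere-dependent theta bursts); preprocessing (notch filtering,
    polyphase resampling, event-locked epoching, baseline correction and
    z-scoring, expectancy categorisation); Morlet-wavelet event-related
    spectral perturbation (ERSP) maps with label-permutation statistics and
    false-discovery-rate correction; a sliding-window multivariate
    ridge-logistic discriminant of outcome valence with leave-one-out ROC area
    (Az), a label-randomisation significance threshold and early/late
    component detection; and behavioural trial-transition and reaction-time
    statistics. A single-call pipeline ties the stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
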