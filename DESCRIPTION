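Package: dntransient
Title: Dynamic Divisive Normalization Model of Visual Change Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-unit excitatory-inhibitory rate circuit in which
    divisive inhibition acts on a slower time scale than excitation, producing
    the pronounced firing-rate transients that motion-selective cortical
    neurons show after sudden stimulus changes. Provides closed-form
    steady-state, peak and attention-modulation results for the circuit, a
    reduced observable parameterization driven by sustained pre- and
    post-change rates, grid-search fitting of the model to spike-train PSTHs
    with chi-square goodness of fit and surrogate calibration, change-transient
    statistics (excess cumulative spike counts with Poisson significance
    envelopes, interval count tests, attention indices, time-advantage
    estimates), and an inhomogeneous-Poisson spike-train generator so the whole
    pipeline can be exercised end-to-end on synthetic data with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
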