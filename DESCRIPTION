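Package: mftfcca
Title: Directed Spectral Information Flow Between Mixed-Frequency Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric estimation of directed spectral information flow
    between time series sampled at different rates, by canonical correlation
    analysis between the short-time Fourier transform of the fast channel and
    the slow channel across signed time lags (MF-TFCCA). Includes simulators
    for linear vector-autoregressive benchmark systems and nonlinear coupled
    systems (phase-amplitude coupling, the two-species logistic map, the
    coupled Rossler-Lorenz system), analytic and estimated spectral Granger
    causality from VAR models, a multi-trial mixed-frequency VAR Granger test,
    phase-randomization surrogate significance testing, and driving-frequency
    attribution by filter-one-frequency-out analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    deSolve,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
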