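Package: calyxatp
Title: Presynaptic Bioenergetics and Transmission-Failure Analysis for
    High-Frequency Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of presynaptic ATP availability during
    sustained high-frequency stimulation and its consequences for
    synaptic transmission, developed for calyx of Held style recordings.
    Provides the relative-ATP consumption ODE with time-varying demand,
    a Hill-function link from ATP level to transmission-failure rate,
    bounded multi-start least-squares estimation of the consumption and
    failure parameters from per-train failure-rate series, standard
    electrophysiology train metrics (paired-pulse ratio, depression and
    recovery time constants, steady-state depression, readily releasable
    pool charge integrals, time to first failure, spontaneous-event
    detection), and a synthetic-data generator that emulates the
    stimulation protocols and stochastic Bernoulli transmission failures
    so that every analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
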