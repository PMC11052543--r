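Package: amha
Title: Three-State Social Contagion Analysis of Drinking Behaviour on Longitudinal Networks
Version: 0.1.0
Authors@R:
    person("FHS", "Modeller", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spread of drinking behaviour through a
    social network using a three-state (abstain, moderate, heavy)
    susceptible-infected-susceptible-type contagion model. Provides state
    classification from self-reported drinks per week, extraction of
    wave-to-wave state transitions with neighbour context, descriptive
    validation statistics (transition matrices, spatial correlation and
    clustering, stability cutoff sweeps), calibration of spontaneous and
    social transition rates by weighted least squares, a well-mixed
    mean-field ODE model, a stochastic discrete-time simulator on static
    networks, multiplicative intervention experiments, and a seeded
    synthetic-data generator that emulates a Framingham-style longitudinal
    panel with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
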