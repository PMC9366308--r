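Package: ctpe
Title: Continuous-Time Dynamic Modelling of Practice Effects in Longitudinal Verbal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits continuous-time latent dynamic models of repeated verbal-learning
    test performance in which the four recall trials of a word-list task are
    correlated stochastic processes and practice effects enter as a latent
    process pulsed at the end of each measurement occasion. Provides exact
    matrix-exponential discretization of the underlying stochastic differential
    equations, Kalman-filter and joint-Gaussian marginal likelihoods for
    irregularly timed occasions with missing trials, hierarchical maximum a
    posteriori estimation with diagnosis-group and covariate moderation and
    correlated random effects, model-implied expectation curves, and a
    synthetic-cohort generator emulating a clinically characterized aging
    study design for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
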