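Package: hopcapacity
Title: Storage Capacity of Hopfield Associative Memories with Autapses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic theory and Monte-Carlo simulation of pattern storage in
    binary Hopfield-type attractor networks whose Hebbian coupling matrix may
    retain its diagonal (autapse) terms. Provides the synchronous sign
    dynamics, closed-form one-step retrieval-error probabilities and their
    large-network asymptotics, spurious-state (false-memory) rejection
    probabilities and the discrimination ratio between them, the
    perfect-recovery storage threshold by numeric root search, Lambert-W
    inversion and logarithmic expansion, exhaustive fixed-point censuses of
    small networks, and an estimator of the exponential fixed-point growth
    rate of random symmetric networks. Includes a command-line interface for
    the analytic, simulation and census workflows.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
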