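Package: forcenet
Title: FORCE Learning for Chaotic Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for First-Order Reduced and Controlled Error (FORCE)
    training of chaotic recurrent neural networks. Provides rate-based
    reservoir layers (echo state networks with and without output feedback,
    and connectome-constrained variants), spiking layers (leaky
    integrate-and-fire, Izhikevich and theta neurons with double-exponential
    synaptic filtering), and a family of recursive least-squares trainers:
    classic FORCE readout training, full-FORCE internal-dynamics matching,
    FORCE decoding of filtered spike trains, and per-neuron constrained
    fitting of recurrent weights to recorded neural traces (effective
    connectivity). Synthetic task generators (sum of sines, Lorenz attractor,
    delayed-response boxcars, teacher-network recordings) and a reproducible
    experiment runner make every trainer testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
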