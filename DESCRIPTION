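Package: scnatree
Title: Joint Copy-Number Calling and Event-Tree Inference for Single-Cell DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical model and Markov chain Monte Carlo machinery for joint
    single-cell copy-number calling and copy-number-event-tree reconstruction
    from shallow whole-genome read-count matrices. Detects multi-cell
    breakpoints from binned corrected read counts, collates bins into segments,
    models segment counts with a Dirichlet-multinomial likelihood attached to a
    tree of copy-number events, and searches tree space with a reversible
    Metropolis-Hastings sampler. Includes a generative simulator with retained
    ground truth and evaluation metrics (copy-number RMSE and a path-difference
    tree distance) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
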