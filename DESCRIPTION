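Package: relclock
Title: Relaxed Molecular Clock Dating with MAD Rooting and Homolog Curation
Version: 0.1.0
Authors@R: person("relclock", "maintainers", email = "relclock@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for divergence-time estimation on protein
    gene trees. Provides minimal ancestor deviation (MAD) rooting, monophyly
    and clade-composition analysis with rank-based subsampling, three
    branch-rate processes (uncorrelated gamma multipliers, autocorrelated
    lognormal, and the mean-reverting CIR diffusion), Bayesian MCMC node-age
    estimation under fossil calibrations and a truncated-normal root prior
    with a per-branch substitution-count likelihood, convergence and
    calibration cross-validation diagnostics, homology-search hit and
    alignment quality-control filters, and seeded synthetic-data generators
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
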