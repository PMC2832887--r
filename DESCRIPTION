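Package: promodyn
Title: Spectral and Stochastic Analysis of Combinatorial Promoter Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a gene promoter as a continuous-time Markov chain over the
    2^N combinations of bound transcription factors and epigenetic marks.
    Provides exact spectral decomposition of the promoter generator
    (autocorrelations, modal power spectra, coherence of oscillatory modes,
    eigenvalue trajectories over concentration sweeps), propagation of
    promoter noise through RNA and protein birth-death cascades (shot noise
    and low-pass filtering), exact joint promoter-RNA steady-state
    distributions by sparse master-equation solves, a thermodynamic dual
    parameterization (state free energies and activation barriers, detailed
    balance and Boltzmann equilibria), steady-state entropy-production
    accounting for energy-driven promoter cycles, and an exact Gillespie
    simulator used as an independent cross-validation oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
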