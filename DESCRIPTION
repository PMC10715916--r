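Package: opinionet
Title: Agent-Based Opinion Dynamics with Social Identity on Homophilic Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates collective opinion formation in a society of agents who
    hold probabilistic opinions over a discretized belief space and carry one
    of two fixed social identities. Agents communicate on a homophilic
    two-ring-lattice network with Watts-Strogatz style link rewiring, update
    opinions through a Bayesian social-influence rule moderated by an
    identity-dependent perception filter (in-group bias), and drift towards
    uncertainty through an implicit diffusion step when not interacting.
    Provides network construction and diagnostics, single-run trajectories,
    seeded Monte Carlo ensembles with consensus-frequency summaries, parameter
    sweeps, YAML/JSON configuration handling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
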