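Package: spermsim
Title: Agent-Based Simulation of Collective Sperm Search and Selection in
    Complex Microenvironments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of self-propelled sperm agents performing
    diffusive search for an egg in bounded, gridded microenvironments,
    including acyclic maze arenas described by their skeleton graphs.
    Implements five empirically parameterised motility classes, per-agent
    calcium oscillators with Poisson-distributed frequencies gating a
    time-homogeneous Markov model of motility-state switching, graph-based
    spatial complexity statistics (total weighted complexity and direct-path
    probability), trajectory summaries (root-mean-square displacement and
    CASA-style velocity metrics), and selection statistics based on Bayesian
    posterior fitness and relative information gain (Kullback-Leibler
    divergence). Replicate sweep drivers reproduce two-factor designs over
    maze complexity and population heterogeneity with ANOVA variance
    partitioning and Tukey post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    e1071,
    optparse
Config/testthat/edition: 3
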