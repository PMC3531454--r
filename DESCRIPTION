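Package: caspike
Title: Hierarchic Semi-Markov Modelling of Intracellular Calcium Spikes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical and stochastic tools for hierarchic stochastic
    modelling of intracellular calcium signalling. Cluster-level IP3 receptor
    dynamics are described by a semi-Markov chain over the number of open
    clusters, with generalized exponential (GE) waiting-time densities whose
    Laplace transforms permit closed computation of stationary occupancies,
    interspike-interval moments and splitting probabilities without inverse
    transforms. Includes the De Young-Keizer single-channel model for deriving
    opening-time densities and Hill-type parameter maps, a delayed
    Gillespie-type trajectory simulator, and a generic inhomogeneous-Poisson
    spike model with refractory recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    fitdistrplus,
    minpack.lm,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
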