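Package: sidechainr
Title: Generative Probabilistic Modelling of Protein Side-Chain Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully continuous, generative probabilistic model of protein
    side-chain chi dihedral angles, optionally conditioned on the backbone
    phi/psi angles. The model is a dynamic Bayesian network with discrete
    hidden nodes and von Mises angular emissions, covering all rotameric
    amino acids in a single parameter set. The package provides maximum
    likelihood training by expectation-maximization (exact and stochastic
    variants) with AIC-based selection of the hidden-node size, exact
    likelihood evaluation via the forward algorithm, ancestral and
    forward-backtrack conditional sampling, Gaussian-mixture rotamer-library
    density evaluation and Kullback-Leibler model comparison, PDB structure
    handling with dihedral extraction and ideal-geometry side-chain
    construction, and Metropolis-Hastings side-chain packing on a fixed
    backbone under a Lennard-Jones 6-12 potential.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
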