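Package: itaml
Title: Information-Theoretic Density Descriptors and Hybrid
    Classical-Quantum Regression for Molecular Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes information-theoretic (ITA) descriptors of molecular
    electron densities by multicenter numerical quadrature: Shannon entropy,
    Fisher information, Ghosh-Berkowitz-Parr entropy, Onicescu information
    energies, relative Renyi entropies, information gain, and the G1/G2/G3
    density-deformation functionals with Hirshfeld stockholder partitioning
    against promolecular references.  Adds molecular-electrostatic-potential
    descriptors at carbonyl oxygen nuclei, Gaussian cube and XYZ readers,
    dataset curation for quinone redox-potential collections, and three
    regression back ends for predicting redox potentials and Hammett
    constants from the 13-dimensional descriptor space: ordinary least
    squares, a compact multilayer perceptron, and a hybrid model built on a
    12-qubit variational quantum circuit simulated exactly by statevector
    evolution with adjoint gradients.  A synthetic benchmark module
    generates toy molecular fields with closed-form descriptor values and
    planted feature/label tables for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
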