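Package: adcfold
Title: Folded ADC(2) Complex Polarization Propagator and Eigensolvers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes UV/vis absorption and electronic circular dichroism
    spectra of small closed-shell molecules at the level of the second-order
    algebraic-diagrammatic construction (ADC(2)) scheme for the polarization
    propagator. Damped (complex polarization propagator) linear response
    equations and the ADC(2) eigenvalue problem are folded onto the
    particle-hole manifold by exact elimination of the diagonal
    two-particle-two-hole block, and solved with iterative subspace
    algorithms: a real-algebra coupled solver for complex response functions
    with common or separate trial-vector subspaces, and a nonlinear block
    eigensolver with Newton-Raphson eigenvalue refinement and controlled
    subspace collapse. Includes a self-contained Hartree-Fock backend with a
    McMurchie-Davidson Gaussian integral engine, batched auxiliary-Fock MO
    integral transformation, modified transition moments through second
    order, oscillator and rotatory strengths, and a synthetic
    model-Hamiltonian generator for backend-free solver testing. Dense
    singles-plus-doubles matrix assembly is provided as a validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
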