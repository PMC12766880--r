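Package: vqerdm
Title: Density-Matrix-Converged Variational Quantum Eigensolvers for
    Molecular Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noiseless statevector simulation of variational quantum
    eigensolvers (VQE) that converge both the electronic energy and the
    one-particle reduced density matrix (1-RDM).  Implements the VQE* dual
    convergence criterion and the VQE-LD density-augmented loss function,
    a minimal-basis (STO-3G) integral engine with restricted Hartree-Fock,
    frozen-core active-space Hamiltonians, the Jordan-Wigner mapping, the
    k-UpCCGSD and GateFabric ansaetze with exact adjoint gradients, a
    determinant-based CASCI reference, and the full chain of 1-RDM-derived
    properties: electron density, electrostatic potential, dipole moments,
    Mulliken populations, Gaussian cube export, and QTAIM critical-point
    analysis of the density topology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
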