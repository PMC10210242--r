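Package: qcasscf
Title: Hybrid Quantum-Classical CASSCF on a Desk-Scale Quantum Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Complete active space self-consistent field (CASSCF) calculations
    in which the active-space eigenproblem is solved either exactly or by a
    simulated variational quantum eigensolver (VQE). Includes a Gaussian
    integral engine (McMurchie-Davidson) for small molecules, restricted and
    restricted open-shell Hartree-Fock, active-space Hamiltonian construction,
    Jordan-Wigner and parity (two-qubit-reduced) fermion-to-qubit mappings,
    statevector simulation of UCCSD and hardware-efficient ansaetze, shot
    sampling with a parameterized depolarizing/readout noise model, SPSA and
    quasi-Newton parameter optimization, reduced-density-matrix measurement and
    post-processing (normalization, symmetrization, canonicalization to natural
    orbitals), first-order orbital optimization, FCIDUMP/XYZ input and output,
    and a benchmark harness for repeated noisy runs comparing canonical and
    noncanonical active orbitals.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
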