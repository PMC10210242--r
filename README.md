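# qcasscf

Hybrid quantum-classical CASSCF on a desk-scale simulator, in R.

Complete-active-space methods keep quantum-computational chemistry inside a
small qubit budget: only a few strongly correlated molecular orbitals (the
*active space*) are handled by the expensive solver, while the rest of the
molecule stays at Hartree-Fock mean field. Selecting an active space is not
enough, though — the orbitals themselves must be re-optimized against the
correlated density (CASSCF), otherwise the result is dominated by the
mean-field description. `qcasscf` implements the whole loop the way a
quantum device would run it:

1. **Molecular setup** — XYZ geometries, bundled STO-3G / 6-31G / cc-pVDZ
   basis tables (H, C, N, O), a McMurchie-Davidson Gaussian integral engine
   (s/p/spherical-d), RHF and ROHF with DIIS.
2. **Active space** — effective Hamiltonian
   `E_core + sum h_pq E_pq + 1/2 sum (pq|rs) e_pqrs` with the inactive space
   folded into a mean field; FCIDUMP import/export (Molpro dialect).
3. **Qubit encodings** — Jordan-Wigner, and parity with two-qubit reduction
   (`2m` or `2m-2` qubits for `m` active orbitals), with a small
   Pauli-string algebra.
4. **Solvers** — exact sector-projected diagonalization (the FCI driver and
   test oracle), statevector UCCSD-VQE, and a hardware-efficient ansatz
   (Ry/Rz + CX chain) with SPSA for noisy objectives.
5. **RDM machinery** — spin-summed 1-/2-RDM measurement; normalization,
   symmetrization, constraint projection, canonicalization to natural
   orbitals.
6. **Orbital optimizer** — generalized-Fock gradient over non-redundant
   rotations, frozen-RDM line-searched updates, monotone noiseless
   macro-iterations, warm starts from smaller active spaces.
7. **Noise benchmark** — density-matrix circuit simulation with
   depolarizing + readout noise and shot sampling; repeated-run statistics
   comparing canonical vs noncanonical active orbitals.

## Worked example: stretched CO, CAS(2,2)

Carbon monoxide stretched to a 1.54 Angstrom bond is strongly correlated
enough that a two-orbital active space already matters:

```r
library(qcasscf)

co   <- parse_xyz("2\nCO stretched\nC 0 0 0\nO 0 0 1.54")
ints <- compute_ao_integrals(co, "cc-pvdz")
scf  <- run_hf(ints)
scf
#> SCF: E = -112.5328439643 Ha, converged = TRUE, n_mo = 28 (7 alpha / 7 beta)

res <- run_casscf(ints, list(n_elec = 2, n_orb = 2), driver = "FCI", scf = scf)
res
#> CASSCF: E = -112.587151558 Ha after 21 macro-iterations (converged = TRUE)
#>   natural occupations: 1.747 0.253
```

The CASSCF energy drops 54 mHa below HF, and the natural occupations
1.747 / 0.253 show the strong static correlation in the active pair.
Replacing the exact active-space driver by the simulated quantum one:

```r
vqe <- run_casscf(ints, list(n_elec = 2, n_orb = 2), driver = "UCCSD-VQE",
                  scf = scf)
vqe$energy
#> [1] -112.5872
```

UCCSD is exact for two orbitals, so the quantum driver lands on the same
minimum to sub-microhartree precision. The noisy pipeline (parity mapping
with two-qubit reduction, hardware-efficient ansatz, SPSA, depolarizing +
readout noise at 1000 shots) is exercised through `bench_config()`,
`run_repeated()` and `compare_canonical()`; a thin command-line wrapper with
`scf` / `casci` / `vqe` / `casscf` / `noisy-bench` / `fcidump` subcommands
lives at `inst/cli/qcasscf.R`.

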