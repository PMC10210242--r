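---
title: "Methods: hybrid quantum-classical CASSCF on a simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid quantum-classical CASSCF on a simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mapping a molecular electronic Hamiltonian onto qubits costs two qubits per
contracted basis function, so even water in a double-zeta basis needs 48
qubits. Complete-active-space (CAS) methods cut this down by treating only a
handful of strongly correlated molecular orbitals (MOs) with the expensive
(here: quantum-simulated) solver while the remaining electrons stay at mean
field. But a fixed active space inherits the Hartree-Fock (HF) orbital
shapes, which describe correlation poorly, especially in large basis sets;
the remedy is CASSCF — re-optimizing the orbitals against the correlated
active-space density. This package implements the full pipeline at
"desk scale": molecular integrals, HF, active-space Hamiltonians, qubit
encodings, statevector and noisy-circuit VQE solvers, reduced-density-matrix
(RDM) post-processing, and the orbital optimizer, together with an exact
diagonalization driver that serves as the internal oracle.

# Electronic-structure layer

AO integrals are evaluated with a McMurchie-Davidson scheme (Hermite
Gaussians, Boys function via the regularized incomplete gamma) for s, p and
spherical d functions; STO-3G, 6-31G and cc-pVDZ for H/C/N/O are bundled as
plain-text shell tables, and any basis in the same format can be supplied as
a file. Coordinates are read in Angstrom and converted at
0.52917721092 Angstrom/Bohr; all energies are Hartree.

The SCF layer does restricted HF with DIIS (convergence: energy change
below 1e-10 Ha and DIIS residual below 1e-8), and restricted open-shell HF
via a Guest-Saunders effective Fock matrix for doublets and higher
multiplicities. Orbitals are ordered by ascending orbital energy; HOMO/LUMO
labels follow the aufbau filling.

An active space is an explicit 1-based MO index list (the
`frontier_indices()` helper builds the HOMO-centred window). The effective
active Hamiltonian is the inactive Fock matrix restricted to the active
block, the active block of the MO two-electron integrals (chemists'
notation), and the core energy `E_nuc + sum_i [h_ii + F^inact_ii]`.
With an empty active space this reduces exactly to the HF energy, which is
one of the package's internal consistency tests.

# Qubit layer

Spin orbitals are blocked (alpha 0..n-1, beta n..2n-1). Two encodings are
provided:

* Jordan-Wigner, with the phase convention
  `a+_j -> (X_j - i Y_j)/2` tensored with a Z chain on qubits below j, so
  statevector amplitudes are reproducible;
* parity with two-qubit reduction. In the parity basis qubit j stores the
  running occupation parity, so with blocked ordering qubit n-1 carries the
  alpha parity and qubit 2n-1 the total parity; in a fixed
  (electron count, 2Sz) sector both are constants and are removed, with the
  sector labels always passed explicitly.

Both mappings are driven by one generic composer that multiplies ladder-
operator images in a small Pauli algebra; the qubit Hamiltonian is assembled
from cached images of the spin-summed excitation operators
`E_pq = sum_s a+_ps a_qs` and pair operators
`e_pqrs = E_pq E_rs - delta_qr E_ps`, so CASSCF macro-iterations (which
change only the integral coefficients) rebuild it cheaply. Coefficient
pruning uses a 1e-12 tolerance.

# Solvers

The exact driver diagonalizes the qubit Hamiltonian restricted to the basis
states of the particle-number/Sz sector (dimension at most
`choose(2n, N)`); the same code path provides reference spectra for the
encoding-equivalence tests.

UCCSD parameterizes every Sz-preserving single and double excitation out of
the aufbau reference with an independent amplitude, matching the common
quantum-software convention. (A spin-adapted singlet parameterization was
considered; the per-spin-orbital form was chosen because it is the ansatz
used by the mainstream VQE stacks this simulator mirrors, and it is exact
for CAS(2,2) either way.) The state is prepared with a single first-order
Trotter step in a fixed order — singles then doubles, lexicographic — and
each generator is exponentiated exactly through its eigendecomposition,
which is precomputed once per ansatz, so Trotter error exists only through
the ordering, not within a generator. At convergence for CAS(2,2) the
ansatz is exact and the variational bound is saturated to 1e-9 Ha.

The hardware-efficient ansatz (HEA) is `L` blocks of
[Ry layer, Rz layer, CX linear chain] closed by a final Ry + Rz layer
(default L = 1), acting on `|0...0>`. The reference hardware circuit is not
fully specified, so any layout reaching the same noiseless minima is
acceptable; this one does for every 2-qubit CAS(2,2) case tested.

Noiseless minimization uses a quasi-Newton (BFGS) optimizer — with an
adjoint-mode analytic energy gradient for UCCSD (one forward and one
backward sweep per gradient), numerical gradients otherwise — starting from
zero amplitudes for UCCSD (the HF point) and from a seeded uniform
(-pi, pi) draw for HEA angles. A few seeded extra starting points guard the
deterministic optimizer against local minima; only the first CASSCF
macro-iteration multi-starts, later ones warm-start from the previous
amplitudes. Under noise the optimizer is
SPSA with the standard gain sequences `a_k = a/(k+1+A)^0.602`,
`c_k = c/k^0.101`, A = 10, c = 0.1 and 60 iterations per macro-iteration by
default; the learning rate is calibrated from five initial gradient samples
so the first update is about 0.1 rad per parameter. Warm starts carry the
optimal parameters from one macro-iteration to the next.

# Noise model

Device noise is a parameterized model: depolarizing channels after every
gate (`rho -> (1-p) rho + p I/2^k`, defaults 1e-3 for one-qubit and 1e-2
for two-qubit gates), a per-qubit readout confusion (default symmetric flip
2e-2), and 1000 shots per Pauli term, sampled multinomially from the exact
noisy outcome distribution of a density-matrix simulation. Distinct Pauli
labels are sampled once per prepared state and shared across the operators
that contain them, as simultaneous readout would. The model reproduces the
order of magnitude of the reference minimum-average-energy errors
(a few times 1e-2 Ha for CAS(2,2) molecules at these defaults) but is not a
calibration of any specific device; calibrated-device dispersion tables are
therefore out of scope.

# RDM post-processing

Measured spin-summed RDMs pass through normalization
(`dm1 <- dm1 * N/tr(dm1)`), symmetrization (`(dm1 + dm1^T)/2`), 2-RDM
constraint enforcement, and canonicalization. Conventions (Mulliken pair
ordering, matching the `(pq|rs)` integrals): `sum_r dm2[p,q,r,r] =
(N-1) dm1[p,q]` and `sum_{p,r} dm2[p,p,r,r] = N(N-1)`. The 2-RDM of a real
wavefunction is symmetric under hermiticity `(p,q,r,s) -> (q,p,s,r)` and
pair exchange `(p,q,r,s) -> (r,s,p,q)` — and, notably, *not* under the full
8-fold ERI group, although the energy is blind to the difference;
`constrain_dm2()` therefore averages over the 4-element group only, rescales
the full trace, and restores the partial trace exactly with the projection
tensor `(delta_rs D_pq + delta_pq D_rs)/n` built from the traceless defect
D. The whole pipeline is idempotent to 1e-12 and leaves exact RDMs
untouched to 1e-10. Under noise, 1-RDM eigenvalues are first clipped into
[0, 2] and rescaled to trace N. Canonicalization diagonalizes the 1-RDM
with descending occupations and a deterministic sign fix (largest-magnitude
eigenvector component positive); noncanonical mode skips exactly this step.

# Orbital optimizer

The optimizer is two-step: solve the active space, then relax orbitals with
the RDMs frozen. The orbital gradient is `2(F - F^T)` over the non-redundant
rotation classes (inactive-active, inactive-virtual, active-virtual;
active-active rotations are redundant at the exact-solver fixed point and
are handled by canonicalization instead), with the generalized Fock matrix
built from the inactive Fock, active Fock, and the `Q` contraction of the
2-RDM with the two-electron integrals. The gradient is validated against
central finite differences of the frozen-RDM energy to 1e-6.

Orbital updates minimize the frozen-RDM energy surrogate with
diagonal-Hessian-preconditioned descent, a quadratic-interpolation line
search, and a 0.2 rad trust cap per element. A plain diagonal-Hessian step
with trust damping was tried first and stalled on near-redundant rotations
involving almost-doubly-occupied active orbitals (energy changes of 1e-9 per
step with gradient norms of 1e-4); the line-searched surrogate minimization
fixes this, and has the attractive property that the subsequent exact CI
re-solve can only lower the surrogate, making noiseless macro-iterations
monotone. Rotations are applied as `C <- C exp(-kappa)`, preserving
overlap-metric orthonormality to machine precision.

Convergence defaults: tight (energy change < 1e-8 Ha *and* gradient norm
< 1e-5 — the gradient threshold is a documented default since only the
energy half is printed in the reference) for noiseless drivers; loose
(energy change < 1e-5 Ha, energy criterion only, iteration cap 9) for the
noisy benchmark. `warm_start()` seeds a larger-active-space run with the
converged orbitals of a smaller one.

# Synthetic data and fixtures

`generate_fixture()` produces exactly solvable active-space Hamiltonians
(dense random with the physical integral symmetries, Hubbard-like chains,
and a 2-orbital stretched-diatomic model) as FCIDUMP files with a JSON
sidecar holding the exact ground energy and natural occupations. The
benchmark geometries that are fully specified in the source text (CO at a
1.54 Angstrom bond) are bundled as-is; water, C2 and HOOO fixtures are
synthetic stand-ins (flagged in their filenames and comment lines) at
standard experimental-style geometries, because the geometries behind the
published reference energies are not distributed with them. Tests against these fixtures assert
relationships (variational bounds, relaxation gains, encoding equivalence),
not the printed absolute energies, which are only reproduced for CO.

Problem sizes used in the test-suite study: CAS(2,2) and CAS(4,4) spaces in
STO-3G/cc-pVDZ (up to 28 MOs), 20 repeats and 9 macro-iterations at 1000
shots for the noise study — the sizes at which the reference
benchmarks are quoted, and comfortably exact-diagonalizable for
cross-checks.

# Known limitations

* ANO-L-VDZP is not bundled (its general contractions are not reproducible
  here); the loader accepts user-provided basis files in the documented
  format. Reference values computed in that basis are accordingly not
  asserted anywhere.
* The noisy benchmark reproduces the *sign* of the canonicalization effect
  on minimum average energies at the default noise point, but both orbital
  modes in this implementation remain stable over 9 iterations: because
  active-active rotations are excluded from the gradient by design, the
  noncanonical mode cannot accumulate active-space drift, which is the
  plausible mechanism behind the reference's noncanonical deconvergence.
  The dispersion-growth contrast is therefore weaker here than in the
  calibrated-device study.
* No point-group symmetry, no DFT reference orbitals, no Bravyi-Kitaev
  encoding, no excited-state or state-averaged CASSCF, no device-topology
  transpilation; statevector/density-matrix simulation is practical to
  ~10 qubits.
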