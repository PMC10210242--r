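# Ansatz state preparation: Hartree-Fock reference, UCCSD (exact per-generator
# operator exponentials, one first-order Trotter step), hardware-efficient
# ansatz (Ry/Rz rotation layers + CX linear-chain entanglers).

#' Hartree-Fock reference state in an encoding
#'
#' Occupies the lowest-index active spin orbitals aufbau-style (alpha excess
#' for open shells) and maps the determinant into the encoding's basis.
#'
#' @param n_orb active spatial orbitals.
#' @param n_alpha,n_beta active alpha/beta electron counts.
#' @param encoding "jw" or "parity" (two-qubit reduced).
#' @return a `qc_statevector` computational basis state.
#' @export
prepare_reference <- function(n_orb, n_alpha, n_beta,
                              encoding = c("jw", "parity")) {
  encoding <- match.arg(encoding)
  occ <- c(seq_len(n_alpha) - 1L,
           if (n_beta > 0) n_orb + seq_len(n_beta) - 1L else integer(0))
  idx <- .occ_to_index(occ, n_orb, encoding)
  nq <- n_qubits_for(n_orb, encoding)
  basis_state(nq, index = idx)
}

# occupied/virtual spin orbitals of the aufbau reference (0-based, blocked)
.ref_spin_orbitals <- function(n_orb, n_alpha, n_beta) {
  occ <- c(seq_len(n_alpha) - 1L,
           if (n_beta > 0) n_orb + seq_len(n_beta) - 1L else integer(0))
  list(occ = occ, virt = setdiff(0:(2L * n_orb - 1L), occ))
}

.spin_of <- function(so, n_orb) ifelse(so < n_orb, 0L, 1L)

#' UCCSD ansatz specification
#'
#' Enumerates all Sz-preserving single and double excitations out of the
#' aufbau reference, one independent parameter each. Generators are applied
#' in a fixed order (singles first, then doubles, each sorted
#' lexicographically by occupied then virtual indices) with a single
#' first-order Trotter step; each generator is exponentiated exactly via its
#' eigendecomposition.
#'
#' @param n_orb active spatial orbitals.
#' @param n_alpha,n_beta active electron counts.
#' @param encoding "jw" or "parity".
#' @return object of class `qc_ansatz` with `kind = "UCCSD"`.
#' @export
uccsd_spec <- function(n_orb, n_alpha, n_beta, encoding = c("jw", "parity")) {
  encoding <- match.arg(encoding)
  n_so <- 2L * n_orb
  ref <- .ref_spin_orbitals(n_orb, n_alpha, n_beta)
  n_elec <- n_alpha + n_beta
  sz2 <- n_alpha - n_beta
  singles <- list()
  for (i in ref$occ) for (a in ref$virt) {
    if (.spin_of(i, n_orb) != .spin_of(a, n_orb)) next
    singles[[length(singles) + 1L]] <- c(i = i, a = a)
  }
  doubles <- list()
  occ2 <- if (length(ref$occ) >= 2) utils::combn(ref$occ, 2) else
    matrix(integer(0), 2, 0)
  virt2 <- if (length(ref$virt) >= 2) utils::combn(ref$virt, 2) else
    matrix(integer(0), 2, 0)
  for (ij in seq_len(ncol(occ2))) for (ab in seq_len(ncol(virt2))) {
    i <- occ2[1, ij]; j <- occ2[2, ij]
    a <- virt2[1, ab]; b <- virt2[2, ab]
    si <- .spin_of(i, n_orb) + .spin_of(j, n_orb)
    sa <- .spin_of(a, n_orb) + .spin_of(b, n_orb)
    if (si != sa) next
    doubles[[length(doubles) + 1L]] <- c(i = i, j = j, a = a, b = b)
  }
  mapper <- function(f) map_to_qubits(f, encoding, n_elec = n_elec, sz2 = sz2)
  gens <- list()
  for (s in singles) {
    f <- fermion_operator(n_so, list(
      .fterm(c(s["a"], s["i"]), c(1L, 0L), 1),
      .fterm(c(s["i"], s["a"]), c(1L, 0L), -1)
    ))
    gens[[length(gens) + 1L]] <- mapper(f)
  }
  for (d in doubles) {
    f <- fermion_operator(n_so, list(
      .fterm(c(d["a"], d["b"], d["j"], d["i"]), c(1L, 1L, 0L, 0L), 1),
      .fterm(c(d["i"], d["j"], d["b"], d["a"]), c(1L, 1L, 0L, 0L), -1)
    ))
    gens[[length(gens) + 1L]] <- mapper(f)
  }
  # exact exponential data: G anti-Hermitian => iG Hermitian = V diag(l) V^H,
  # exp(theta G) = V diag(exp(-i theta l)) V^H
  expdata <- lapply(gens, function(g) {
    Gm <- qop_matrix(g)
    Hm <- (0+1i) * Gm
    Hm <- (Hm + Conj(t(Hm))) / 2
    ev <- eigen(Hm)
    list(V = ev$vectors, lambda = Re(ev$values))
  })
  structure(list(
    kind = "UCCSD", encoding = encoding, n_orb = n_orb,
    n_alpha = n_alpha, n_beta = n_beta,
    n_qubits = n_qubits_for(n_orb, encoding),
    n_params = length(gens),
    excitations = list(singles = singles, doubles = doubles),
    generators = gens, expdata = expdata,
    reference = prepare_reference(n_orb, n_alpha, n_beta, encoding)
  ), class = "qc_ansatz")
}

#' Apply the UCCSD ansatz
#' @param ref reference `qc_statevector` (defaults to the spec's HF state).
#' @param params amplitude vector, one per generator.
#' @param spec a UCCSD `qc_ansatz`.
#' @return a normalized `qc_statevector`.
#' @export
apply_uccsd <- function(ref = NULL, params, spec) {
  stopifnot(spec$kind == "UCCSD", length(params) == spec$n_params)
  amps <- (if (is.null(ref)) spec$reference else ref)$amps
  for (k in seq_along(params)) {
    if (params[k] == 0) next
    ed <- spec$expdata[[k]]
    amps <- ed$V %*% (exp(-1i * params[k] * ed$lambda) *
                        (Conj(t(ed$V)) %*% amps))
    amps <- drop(amps)
  }
  statevector(amps)
}

#' Hardware-efficient ansatz specification
#'
#' Layout: L blocks of [Ry layer, Rz layer, CX linear chain], closed by a
#' final Ry + Rz layer; parameter count (L + 1) * 2 * n_qubits. All rotations
#' start from |0...0>.
#'
#' @param n_qubits qubit count.
#' @param n_layers number of entangling blocks L.
#' @return object of class `qc_ansatz` with `kind = "HEA"`.
#' @export
hea_spec <- function(n_qubits, n_layers = 1L) {
  structure(list(
    kind = "HEA", n_qubits = as.integer(n_qubits),
    n_layers = as.integer(n_layers),
    n_params = (n_layers + 1L) * 2L * n_qubits
  ), class = "qc_ansatz")
}

#' Gate list of the hardware-efficient circuit
#' @param params rotation angles.
#' @param spec a HEA `qc_ansatz`.
#' @return list of gates `list(type, qubits, angle)`.
#' @export
hea_gates <- function(params, spec) {
  stopifnot(spec$kind == "HEA", length(params) == spec$n_params)
  n <- spec$n_qubits
  gates <- list()
  k <- 0L
  add <- function(type, qubits, angle = NULL) {
    gates[[length(gates) + 1L]] <<- list(type = type, qubits = qubits,
                                         angle = angle)
  }
  for (layer in seq_len(spec$n_layers + 1L)) {
    for (q in 0:(n - 1L)) { k <- k + 1L; add("ry", q, params[k]) }
    for (q in 0:(n - 1L)) { k <- k + 1L; add("rz", q, params[k]) }
    if (layer <= spec$n_layers && n >= 2L) {
      for (q in 0:(n - 2L)) add("cx", c(q, q + 1L))
    }
  }
  gates
}

#' Apply the hardware-efficient ansatz (statevector, noiseless)
#' @inheritParams hea_gates
#' @return a `qc_statevector`.
#' @export
apply_hea <- function(params, spec) {
  state <- basis_state(spec$n_qubits)
  for (g in hea_gates(params, spec)) {
    state <- switch(g$type,
      ry = gate_ry(state, g$qubits[1], g$angle),
      rz = gate_rz(state, g$qubits[1], g$angle),
      cx = gate_cx(state, g$qubits[1], g$qubits[2]),
      stop("unknown gate ", g$type))
  }
  state
}

# Adjoint-mode analytic gradient of <psi(theta)| H |psi(theta)> for the
# UCCSD circuit: one forward sweep storing intermediate states, one backward
# sweep with the daggered exponentials; grad_k = 2 Re <chi_k| G_k |psi_k>.
uccsd_energy_gradient <- function(params, spec, hamiltonian) {
  K <- spec$n_params
  states <- vector("list", K + 1L)
  states[[1]] <- spec$reference$amps
  for (k in seq_len(K)) {
    ed <- spec$expdata[[k]]
    states[[k + 1L]] <- drop(ed$V %*% (exp(-1i * params[k] * ed$lambda) *
                                         (Conj(t(ed$V)) %*% states[[k]])))
  }
  psi <- statevector(states[[K + 1L]])
  hpsi <- apply_qubit_operator(psi, hamiltonian)$amps
  energy <- Re(sum(Conj(psi$amps) * hpsi))
  grad <- numeric(K)
  chi <- hpsi
  for (k in rev(seq_len(K))) {
    ed <- spec$expdata[[k]]
    # chi currently = U_{k+1}^dag ... U_K^dag H psi; G_k = V diag(-i l) V^dag
    gpsi <- drop(ed$V %*% ((-1i * ed$lambda) * (Conj(t(ed$V)) %*% states[[k + 1L]])))
    grad[k] <- 2 * Re(sum(Conj(chi) * gpsi))
    chi <- drop(ed$V %*% (exp(1i * params[k] * ed$lambda) *
                            (Conj(t(ed$V)) %*% chi)))
  }
  list(energy = energy, gradient = grad)
}

#' Prepare the ansatz state for a parameter vector
#' @param params parameter vector.
#' @param spec a `qc_ansatz`.
#' @return a `qc_statevector`.
#' @export
ansatz_state <- function(params, spec) {
  if (spec$kind == "UCCSD") apply_uccsd(NULL, params, spec)
  else apply_hea(params, spec)
}
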