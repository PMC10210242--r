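# Exact active-space eigenstates by sector-projected diagonalization of the
# mapped qubit Hamiltonian; also exact spin-summed RDMs.

# all occupation bitstrings (over 2n spin orbitals, blocked ordering) with
# n_alpha alpha and n_beta beta electrons; returns a list of 0-based
# occupied-index vectors
.sector_occupations <- function(n_orb, n_elec, sz2) {
  if ((n_elec + sz2) %% 2L != 0L || abs(sz2) > n_elec) {
    stop("invalid sector: n_elec = ", n_elec, ", sz2 = ", sz2)
  }
  n_alpha <- (n_elec + sz2) %/% 2L
  n_beta <- (n_elec - sz2) %/% 2L
  if (n_alpha > n_orb || n_beta > n_orb) stop("sector exceeds orbital count")
  choose_idx <- function(k) {
    if (k == 0L) return(list(integer(0)))
    cmb <- utils::combn(n_orb, k)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i] - 1L)
  }
  occs <- list()
  for (a in choose_idx(n_alpha)) {
    for (b in choose_idx(n_beta)) {
      occs[[length(occs) + 1L]] <- c(a, b + n_orb)
    }
  }
  occs
}

# encoding-space basis index (0-based) of an occupation set
.occ_to_index <- function(occ_bits, n_orb, encoding) {
  n_so <- 2L * n_orb
  n <- integer(n_so)
  n[occ_bits + 1L] <- 1L
  if (encoding == "jw") {
    return(sum(2^(which(n == 1L) - 1L)))
  }
  p <- cumsum(n) %% 2L
  fixed <- .parity_fixed_qubits(n_so) + 1L
  p <- p[-fixed]
  sum(2^(which(p == 1L) - 1L))
}

#' Basis indices of a particle-number/Sz sector
#'
#' @param n_orb active spatial orbitals.
#' @param n_elec electrons in the sector.
#' @param sz2 twice the Sz projection.
#' @param encoding "jw" (2 n_orb qubits) or "parity" (reduced, 2 n_orb - 2).
#' @return integer vector of 0-based basis indices.
#' @export
sector_basis <- function(n_orb, n_elec, sz2, encoding = c("jw", "parity")) {
  encoding <- match.arg(encoding)
  occs <- .sector_occupations(n_orb, n_elec, sz2)
  vapply(occs, .occ_to_index, numeric(1), n_orb = n_orb, encoding = encoding)
}

# dense matrix of a qubit operator restricted to a set of basis indices
.op_in_subspace <- function(op, idx) {
  d <- length(idx)
  pos <- integer(2^op$n_qubits)
  pos[idx + 1L] <- seq_len(d)
  M <- matrix(0+0i, d, d)
  masks <- .qop_masks(op)
  for (k in seq_along(op$labels)) {
    flip <- bitwOr(masks$x[k], masks$y[k])
    tgt <- bitwXor(as.integer(idx), flip)
    inside <- pos[tgt + 1L] > 0L
    if (!any(inside)) next
    par <- .popcount(bitwAnd(as.integer(idx), bitwOr(masks$y[k], masks$z[k])))
    ny <- .popcount(masks$y[k])
    phase <- (0+1i)^(ny %% 4L) * (-1)^(par %% 2L)
    src_pos <- seq_len(d)[inside]
    tgt_pos <- pos[tgt + 1L][inside]
    M[cbind(tgt_pos, src_pos)] <- M[cbind(tgt_pos, src_pos)] +
      op$coefs[k] * phase[inside]
  }
  M
}

#' Exact ground state in a symmetry sector
#'
#' Diagonalizes the qubit Hamiltonian restricted to the basis states of the
#' (n_electrons, 2Sz) sector.
#'
#' @param op a Hermitian `qc_qubit_op` (an active-space Hamiltonian).
#' @param sector list with `n_electrons` and `sz2`.
#' @param n_orb number of active spatial orbitals.
#' @param encoding encoding `op` was produced with.
#' @return list: `energy` (lowest sector eigenvalue, includes any identity
#'   offset carried by `op`), `state` (a `qc_statevector` in the encoding
#'   space), `eigenvalues` (all sector eigenvalues, ascending).
#' @export
ground_state <- function(op, sector, n_orb, encoding = c("jw", "parity")) {
  encoding <- match.arg(encoding)
  idx <- sector_basis(n_orb, sector$n_electrons, sector$sz2, encoding)
  if (length(idx) == 0L) stop("empty sector")
  M <- .op_in_subspace(op, idx)
  herm_err <- max(abs(M - Conj(t(M))))
  if (herm_err > 1e-8) stop("Hamiltonian not Hermitian in the sector basis")
  ev <- eigen((M + Conj(t(M))) / 2)
  ord <- order(Re(ev$values))
  vals <- Re(ev$values)[ord]
  vec <- ev$vectors[, ord[1]]
  amps <- rep(0+0i, 2^op$n_qubits)
  amps[idx + 1L] <- vec
  list(energy = vals[1], state = statevector(amps), eigenvalues = vals)
}

#' All sector eigenvalues (for encoding-equivalence checks)
#' @inheritParams ground_state
#' @return ascending numeric vector.
#' @export
sector_spectrum <- function(op, sector, n_orb, encoding = c("jw", "parity")) {
  ground_state(op, sector, n_orb, encoding)$eigenvalues
}

#' Exact spin-summed RDMs of a statevector
#'
#' dm1[p,q] = <E_pq>, dm2[p,q,r,s] = <E_pq E_rs - delta_qr E_ps>.
#'
#' @param state a normalized `qc_statevector`.
#' @param n_orb active spatial orbitals.
#' @param encoding encoding of the state.
#' @param n_elec,sz2 sector labels (parity encoding only).
#' @return a `qc_rdm_pair`.
#' @export
exact_rdms <- function(state, n_orb, encoding = c("jw", "parity"),
                       n_elec = NULL, sz2 = NULL) {
  encoding <- match.arg(encoding)
  ops <- rdm_component_operators(n_orb, encoding, n_elec = n_elec, sz2 = sz2)
  measure_rdms(state, ops)
}
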