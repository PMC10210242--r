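# Second-quantized fermionic operators over active-space spin orbitals.
# Spin-orbital ordering is blocked: alpha spin orbitals are 0..n-1, beta are
# n..2n-1, where n is the number of active spatial orbitals.

#' Construct a fermionic operator
#'
#' @param n_spin_orbitals number of spin orbitals.
#' @param terms list of terms; each term is `list(ops =, coef =)` where `ops`
#'   is an integer matrix with columns `idx` (0-based spin-orbital index) and
#'   `dag` (1 = creation, 0 = annihilation), rows applied left to right as
#'   written (leftmost row acts last on a ket, as in standard operator
#'   notation read right-to-left? No: rows are listed in operator order, the
#'   first row is the leftmost operator).
#' @return object of class `qc_fermion_op`.
#' @export
fermion_operator <- function(n_spin_orbitals, terms = list()) {
  for (t in terms) {
    if (length(t$ops) && max(t$ops[, 1]) >= n_spin_orbitals) {
      stop("spin-orbital index out of range")
    }
  }
  structure(list(n_spin_orbitals = as.integer(n_spin_orbitals), terms = terms),
            class = "qc_fermion_op")
}

.fterm <- function(idx, dag, coef) {
  list(ops = cbind(idx = as.integer(idx), dag = as.integer(dag)), coef = coef)
}

#' Spin-orbital second-quantized form of an active-space Hamiltonian
#'
#' Expands the spatial-orbital effective one-body matrix and two-body tensor
#' over blocked spin orbitals (all alpha, then all beta):
#' sum_{pq,s} h_pq a+_{ps} a_{qs}
#' + 1/2 sum_{pqrs,st} (pq|rs) a+_{ps} a+_{rt} a_{st} a_{qs'} (chemists'
#' notation), plus the core energy on the identity.
#'
#' @param h_act a `qc_active_hamiltonian` (see [build_active_hamiltonian()]),
#'   or a list with `h_eff`, `g_act`, `e_core`.
#' @return a `qc_fermion_op` on 2 x n_active_orbitals spin orbitals.
#' @export
to_spin_orbitals <- function(h_act) {
  h <- h_act$h_eff
  g <- h_act$g_act
  n <- nrow(h)
  nso <- 2L * n
  terms <- list()
  if (!is.null(h_act$e_core) && h_act$e_core != 0) {
    terms[[length(terms) + 1L]] <- .fterm(integer(0), integer(0), h_act$e_core)
  }
  so <- function(p, spin) p - 1L + spin * n  # spin 0 = alpha, 1 = beta
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (h[p, q] == 0) next
    for (s in 0:1) {
      terms[[length(terms) + 1L]] <-
        .fterm(c(so(p, s), so(q, s)), c(1L, 0L), h[p, q])
    }
  }
  if (!is.null(g) && length(g)) {
    for (p in seq_len(n)) for (q in seq_len(n)) {
      for (r in seq_len(n)) for (s in seq_len(n)) {
        coef <- g[p, q, r, s]
        if (coef == 0) next
        for (s1 in 0:1) for (s2 in 0:1) {
          # a+_{p s1} a+_{r s2} a_{s s2} a_{q s1}
          terms[[length(terms) + 1L]] <- .fterm(
            c(so(p, s1), so(r, s2), so(s, s2), so(q, s1)),
            c(1L, 1L, 0L, 0L), coef / 2)
        }
      }
    }
  }
  fermion_operator(nso, terms)
}

# Dense Fock-space matrix of a fermionic operator, built directly from the
# occupation-number representation (independent of any qubit encoding):
# a+_j |n> = (-1)^{sum_{k<j} n_k} (1 - n_j) |... n_j = 1 ...>.
# Basis index b: bit j of b = occupation of spin orbital j.
.fermion_matrix <- function(f) {
  n <- f$n_spin_orbitals
  N <- 2L^n
  M <- matrix(0+0i, N, N)
  for (t in f$terms) {
    ops <- t$ops
    # start from every basis state, apply rightmost operator first
    vec_idx <- 0:(N - 1L)
    amp <- rep(as.complex(t$coef), N)
    state <- vec_idx
    alive <- rep(TRUE, N)
    if (nrow(ops)) {
      for (k in rev(seq_len(nrow(ops)))) {
        j <- ops[k, 1]; dag <- ops[k, 2]
        occ <- bitwAnd(bitwShiftR(state, j), 1L)
        ok <- if (dag == 1L) occ == 0L else occ == 1L
        alive <- alive & ok
        sgn_mask <- 2L^j - 1L
        par <- .popcount(bitwAnd(state, sgn_mask)) %% 2L
        amp <- amp * (-1)^par
        state <- bitwXor(state, bitwShiftL(1L, j)) * 1L
        state[!alive] <- 0L
      }
    }
    idx <- which(alive)
    if (length(idx)) {
      M[cbind(state[idx] + 1L, vec_idx[idx] + 1L)] <-
        M[cbind(state[idx] + 1L, vec_idx[idx] + 1L)] + amp[idx]
    }
  }
  M
}

#' @export
print.qc_fermion_op <- function(x, ...) {
  cat(sprintf("FermionOperator on %d spin orbitals, %d terms\n",
              x$n_spin_orbitals, length(x$terms)))
  invisible(x)
}
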