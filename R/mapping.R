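# Fermion-to-qubit encodings: Jordan-Wigner, and parity with two-qubit
# reduction. Spin-orbital j maps to qubit j (blocked ordering: alpha qubits
# 0..n-1, beta qubits n..2n-1). JW phase convention:
#   a+_j -> (X_j - i Y_j)/2 (x) Z-chain on qubits < j.
# Parity basis stores running parities p_j = n_0 xor ... xor n_j, so qubit
# n-1 carries the alpha-electron parity and qubit 2n-1 the total parity; in a
# fixed (n_elec, 2Sz) symmetry sector both are constants and can be removed.

.ladder_label <- function(n, chars, positions) {
  lab <- rep("I", n)
  lab[positions + 1L] <- chars
  paste0(lab, collapse = "")
}

# images of a_j / a+_j as QubitOperators under an encoding
.ladder_images <- function(n_so, encoding = c("jw", "parity")) {
  encoding <- match.arg(encoding)
  out <- vector("list", n_so)
  for (j0 in 0:(n_so - 1L)) {
    if (encoding == "jw") {
      zchain <- if (j0 > 0) 0:(j0 - 1L) else integer(0)
      labX <- .ladder_label(n_so, c(rep("Z", length(zchain)), "X"),
                            c(zchain, j0))
      labY <- .ladder_label(n_so, c(rep("Z", length(zchain)), "Y"),
                            c(zchain, j0))
      create <- qubit_operator(n_so, c(labX, labY), c(0.5, -0.5i))
    } else {
      xchain <- if (j0 < n_so - 1L) (j0 + 1L):(n_so - 1L) else integer(0)
      zprev <- if (j0 > 0) j0 - 1L else integer(0)
      labX <- .ladder_label(n_so, c(rep("X", length(xchain)), "X",
                                    rep("Z", length(zprev))),
                            c(xchain, j0, zprev))
      labY <- .ladder_label(n_so, c(rep("X", length(xchain)), "Y"),
                            c(xchain, j0))
      create <- qubit_operator(n_so, c(labX, labY), c(0.5, -0.5i))
    }
    out[[j0 + 1L]] <- list(create = create, annihilate = qop_dagger(create))
  }
  out
}

.map_fermion_with_images <- function(f, images, n_so) {
  acc_labels <- character(0)
  acc_coefs <- complex(0)
  for (t in f$terms) {
    op <- qop_identity(n_so, t$coef)
    if (nrow(t$ops)) {
      for (k in seq_len(nrow(t$ops))) {
        img <- images[[t$ops[k, 1] + 1L]]
        fac <- if (t$ops[k, 2] == 1L) img$create else img$annihilate
        op <- qop_mul(op, fac, simplify = FALSE)
      }
    }
    acc_labels <- c(acc_labels, op$labels)
    acc_coefs <- c(acc_coefs, op$coefs)
  }
  simplify_qop(qubit_operator(n_so, acc_labels, acc_coefs))
}

#' Jordan-Wigner transform of a fermionic operator
#'
#' @param f a `qc_fermion_op`.
#' @return a `qc_qubit_op` on `f$n_spin_orbitals` qubits; spectrum-preserving,
#'   Hermitian input yields Hermitian output.
#' @export
jordan_wigner <- function(f) {
  .map_fermion_with_images(f, .ladder_images(f$n_spin_orbitals, "jw"),
                           f$n_spin_orbitals)
}

# qubits removed by the two-qubit reduction (0-based): alpha-parity qubit and
# total-parity qubit
.parity_fixed_qubits <- function(n_so) c(n_so %/% 2L - 1L, n_so - 1L)

#' Parity transform with two-qubit reduction
#'
#' Maps the operator to the parity basis and removes the alpha-parity and
#' total-parity qubits, replacing their Z operators by the sector eigenvalues
#' determined by `n_elec` and `sz2` (= 2 Sz, alpha minus beta count).
#'
#' @param f a `qc_fermion_op` commuting with particle number and Sz.
#' @param n_elec electron number of the target sector.
#' @param sz2 twice the Sz of the target sector.
#' @return a `qc_qubit_op` on `n_spin_orbitals - 2` qubits.
#' @export
parity_map_reduced <- function(f, n_elec, sz2) {
  n_so <- f$n_spin_orbitals
  if ((n_elec + sz2) %% 2L != 0L) stop("n_elec and sz2 have mismatched parity")
  q <- .map_fermion_with_images(f, .ladder_images(n_so, "parity"), n_so)
  fixed <- .parity_fixed_qubits(n_so)
  n_alpha <- (n_elec + sz2) %/% 2L
  eig <- c((-1)^n_alpha, (-1)^n_elec)
  codes <- .labels_to_codes(q$labels)
  coefs <- q$coefs
  if (nrow(codes)) {
    for (k in seq_along(fixed)) {
      col <- codes[, fixed[k] + 1L]
      if (any(col == 1L | col == 2L)) {
        stop("operator does not respect the (n_elec, sz2) sector symmetry")
      }
      coefs <- coefs * ifelse(col == 3L, eig[k], 1)
    }
    codes <- codes[, -(fixed + 1L), drop = FALSE]
  }
  simplify_qop(qubit_operator(n_so - 2L, .codes_to_labels(codes), coefs))
}

#' Map a fermionic operator to qubits
#'
#' @param f a `qc_fermion_op`.
#' @param encoding "jw" or "parity" (parity implies two-qubit reduction).
#' @param n_elec,sz2 sector labels, required for the parity encoding.
#' @return a `qc_qubit_op`.
#' @export
map_to_qubits <- function(f, encoding = c("jw", "parity"),
                          n_elec = NULL, sz2 = NULL) {
  encoding <- match.arg(encoding)
  if (encoding == "jw") return(jordan_wigner(f))
  if (is.null(n_elec) || is.null(sz2)) {
    stop("parity encoding requires explicit n_elec and sz2")
  }
  parity_map_reduced(f, n_elec, sz2)
}

#' Number of qubits used by an encoding
#' @param n_active_orbitals active spatial orbital count.
#' @param encoding "jw" or "parity".
#' @return integer qubit count: 2 m for JW, 2 m - 2 for reduced parity.
#' @export
n_qubits_for <- function(n_active_orbitals, encoding = c("jw", "parity")) {
  encoding <- match.arg(encoding)
  if (encoding == "jw") 2L * n_active_orbitals else 2L * n_active_orbitals - 2L
}

# --- cached spin-summed excitation-operator images -------------------------

.qop_cache <- new.env(parent = emptyenv())

.cache_key <- function(n_orb, encoding, n_elec, sz2) {
  if (encoding == "jw") paste0("jw_", n_orb)
  else paste0("parity_", n_orb, "_", n_elec, "_", sz2)
}

#' Qubit images of the spin-summed RDM component operators
#'
#' Returns the mapped one-body excitation operators
#' E_pq = sum_s a+_{ps} a_{qs} and the two-body pair operators
#' e_pqrs = E_pq E_rs - delta_qr E_ps used to measure spin-summed RDMs.
#'
#' @param n_orb number of active spatial orbitals.
#' @param encoding "jw" or "parity".
#' @param n_elec,sz2 sector labels (parity encoding only).
#' @return list with `E` (n_orb^2 operators, index `[[p]][[q]]`) and `e`
#'   (4-index list `[[p]][[q]][[r]][[s]]`).
#' @export
rdm_component_operators <- function(n_orb, encoding = c("jw", "parity"),
                                    n_elec = NULL, sz2 = NULL) {
  encoding <- match.arg(encoding)
  key <- paste0("rdm_", .cache_key(n_orb, encoding, n_elec, sz2))
  if (!is.null(.qop_cache[[key]])) return(.qop_cache[[key]])
  n_so <- 2L * n_orb
  mapper <- function(f) map_to_qubits(f, encoding, n_elec = n_elec, sz2 = sz2)
  E <- vector("list", n_orb)
  for (p in seq_len(n_orb)) {
    E[[p]] <- vector("list", n_orb)
    for (q in seq_len(n_orb)) {
      f <- fermion_operator(n_so, list(
        .fterm(c(p - 1L, q - 1L), c(1L, 0L), 1),
        .fterm(c(p - 1L + n_orb, q - 1L + n_orb), c(1L, 0L), 1)
      ))
      E[[p]][[q]] <- mapper(f)
    }
  }
  e <- vector("list", n_orb)
  nq <- E[[1]][[1]]$n_qubits
  for (p in seq_len(n_orb)) {
    e[[p]] <- vector("list", n_orb)
    for (q in seq_len(n_orb)) {
      e[[p]][[q]] <- vector("list", n_orb)
      for (r in seq_len(n_orb)) {
        e[[p]][[q]][[r]] <- vector("list", n_orb)
        for (s in seq_len(n_orb)) {
          op <- qop_mul(E[[p]][[q]], E[[r]][[s]])
          if (q == r) op <- qop_add(op, qop_scale(E[[p]][[s]], -1))
          e[[p]][[q]][[r]][[s]] <- op
        }
      }
    }
  }
  out <- list(E = E, e = e, n_orb = n_orb, encoding = encoding,
              n_qubits = nq)
  .qop_cache[[key]] <- out
  out
}

#' Qubit Hamiltonian of an active space
#'
#' Assembles e_core * I + sum_pq h_pq E_pq + 1/2 sum_pqrs (pq|rs) e_pqrs
#' from the cached qubit images of the excitation operators, so repeated
#' builds with updated integrals (as in CASSCF macro-iterations) are cheap.
#'
#' @param h_act a `qc_active_hamiltonian`.
#' @param encoding "jw" or "parity".
#' @param sz2 twice Sz (parity encoding; defaults to 0/1 by electron parity).
#' @return a `qc_qubit_op`.
#' @export
qubit_hamiltonian <- function(h_act, encoding = c("jw", "parity"), sz2 = NULL) {
  encoding <- match.arg(encoding)
  n <- h_act$n_active_orbitals
  if (is.null(sz2)) sz2 <- h_act$n_active_electrons %% 2L
  ops <- rdm_component_operators(n, encoding,
                                 n_elec = h_act$n_active_electrons, sz2 = sz2)
  nq <- ops$n_qubits
  labels <- strrep("I", nq)
  coefs <- as.complex(h_act$e_core)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    cpq <- h_act$h_eff[p, q]
    if (abs(cpq) > 0) {
      op <- ops$E[[p]][[q]]
      labels <- c(labels, op$labels)
      coefs <- c(coefs, op$coefs * cpq)
    }
    for (r in seq_len(n)) for (s in seq_len(n)) {
      cg <- h_act$g_act[p, q, r, s]
      if (abs(cg) > 0) {
        op <- ops$e[[p]][[q]][[r]][[s]]
        labels <- c(labels, op$labels)
        coefs <- c(coefs, op$coefs * (cg / 2))
      }
    }
  }
  simplify_qop(qubit_operator(nq, labels, coefs))
}
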