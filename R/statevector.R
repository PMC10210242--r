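# Statevector simulation. Basis index b (0-based): bit j of b = state of
# qubit j; amplitude vector holds index b at position b + 1.

#' Construct a statevector
#' @param amps complex amplitude vector of length 2^n.
#' @return object of class `qc_statevector`.
#' @export
statevector <- function(amps) {
  n <- as.integer(round(log2(length(amps))))
  if (2^n != length(amps)) stop("amplitude length must be a power of 2")
  structure(list(amps = as.complex(amps), n_qubits = n),
            class = "qc_statevector")
}

#' Computational basis state
#' @param n_qubits qubit count.
#' @param bits 0-based indices of qubits set to 1, or a single basis index
#'   given as `index = `.
#' @param index 0-based basis index (alternative to `bits`).
#' @return a `qc_statevector`.
#' @export
basis_state <- function(n_qubits, bits = integer(0), index = NULL) {
  if (is.null(index)) index <- sum(2^bits)
  amps <- rep(0+0i, 2^n_qubits)
  amps[index + 1] <- 1
  statevector(amps)
}

#' Norm of a statevector
#' @param state a `qc_statevector`.
#' @return L2 norm.
#' @export
sv_norm <- function(state) sqrt(sum(Mod(state$amps)^2))

#' Apply a qubit operator to a statevector
#' @param state a `qc_statevector`.
#' @param op a `qc_qubit_op` on the same qubit count.
#' @return a `qc_statevector` (not normalized in general).
#' @export
apply_qubit_operator <- function(state, op) {
  if (op$n_qubits != state$n_qubits) stop("qubit counts differ")
  masks <- .qop_masks(op)
  out <- rep(0+0i, length(state$amps))
  for (k in seq_along(op$labels)) {
    out <- out + op$coefs[k] *
      cpp_apply_pauli(state$amps, masks$x[k], masks$y[k], masks$z[k])
  }
  statevector(out)
}

#' Exact expectation value
#' @param state a normalized `qc_statevector`.
#' @param op a Hermitian `qc_qubit_op`.
#' @param check check Hermiticity of `op`.
#' @return real expectation value.
#' @export
expectation <- function(state, op, check = FALSE) {
  if (check && !qop_is_hermitian(op)) stop("operator is not Hermitian")
  val <- sum(Conj(state$amps) * apply_qubit_operator(state, op)$amps)
  Re(val)
}

#' Complex expectation value (for non-Hermitian operators)
#' @inheritParams expectation
#' @return complex value <state| op |state>.
#' @export
expectation_complex <- function(state, op) {
  sum(Conj(state$amps) * apply_qubit_operator(state, op)$amps)
}

# --- single- and two-qubit gates -------------------------------------------

.gate_pair_idx <- function(n, q) {
  all_idx <- 0:(2^n - 1L)
  i0 <- all_idx[bitwAnd(all_idx, bitwShiftL(1L, q)) == 0L]
  list(i0 = i0 + 1L, i1 = i0 + 2L^q + 1L)
}

#' Apply an Ry rotation
#' @param state a `qc_statevector`.
#' @param q 0-based qubit index.
#' @param theta rotation angle (radians).
#' @return rotated `qc_statevector`.
#' @export
gate_ry <- function(state, q, theta) {
  p <- .gate_pair_idx(state$n_qubits, q)
  a <- state$amps
  c0 <- cos(theta / 2); s0 <- sin(theta / 2)
  new0 <- c0 * a[p$i0] - s0 * a[p$i1]
  new1 <- s0 * a[p$i0] + c0 * a[p$i1]
  a[p$i0] <- new0; a[p$i1] <- new1
  statevector(a)
}

#' Apply an Rz rotation
#' @inheritParams gate_ry
#' @return rotated `qc_statevector`.
#' @export
gate_rz <- function(state, q, theta) {
  p <- .gate_pair_idx(state$n_qubits, q)
  a <- state$amps
  a[p$i0] <- a[p$i0] * exp(-1i * theta / 2)
  a[p$i1] <- a[p$i1] * exp(1i * theta / 2)
  statevector(a)
}

#' Apply a CNOT gate
#' @param state a `qc_statevector`.
#' @param control,target 0-based qubit indices.
#' @return transformed `qc_statevector`.
#' @export
gate_cx <- function(state, control, target) {
  n <- state$n_qubits
  all_idx <- 0:(2^n - 1L)
  sel <- bitwAnd(all_idx, bitwShiftL(1L, control)) != 0L &
    bitwAnd(all_idx, bitwShiftL(1L, target)) == 0L
  i0 <- all_idx[sel] + 1L
  i1 <- all_idx[sel] + 2^target + 1L
  a <- state$amps
  tmp <- a[i0]; a[i0] <- a[i1]; a[i1] <- tmp
  statevector(a)
}

#' Apply a Hadamard gate
#' @inheritParams gate_ry
#' @return transformed `qc_statevector`.
#' @export
gate_h <- function(state, q) {
  p <- .gate_pair_idx(state$n_qubits, q)
  a <- state$amps
  s <- 1 / sqrt(2)
  new0 <- s * (a[p$i0] + a[p$i1])
  new1 <- s * (a[p$i0] - a[p$i1])
  a[p$i0] <- new0; a[p$i1] <- new1
  statevector(a)
}

#' Apply an S-dagger (inverse phase) gate
#' @inheritParams gate_ry
#' @return transformed `qc_statevector`.
#' @export
gate_sdg <- function(state, q) {
  p <- .gate_pair_idx(state$n_qubits, q)
  a <- state$amps
  a[p$i1] <- a[p$i1] * (-1i)
  statevector(a)
}

#' @export
print.qc_statevector <- function(x, ...) {
  cat(sprintf("Statevector on %d qubits (norm %.12f)\n", x$n_qubits,
              sv_norm(x)))
  invisible(x)
}
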