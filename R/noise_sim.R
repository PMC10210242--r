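# Density-matrix simulation of small noisy circuits: gates as unitaries with
# depolarizing channels after every gate, readout confusion, multinomial shot
# sampling. Intended for the few-qubit hardware-efficient circuits of the
# noisy CASSCF benchmark.

.u_ry <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2),
           -sin(theta / 2), cos(theta / 2)), 2, 2)
}
.u_rz <- function(theta) diag(c(exp(-1i * theta / 2), exp(1i * theta / 2)))
.u_h <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
.u_sdg <- diag(c(1, -1i))
# CX in the qubit-0-is-least-significant-bit convention, control c, target t
.u_cx <- function(n, ctrl, tgt) {
  N <- 2^n
  U <- matrix(0, N, N)
  src <- 0:(N - 1L)
  on <- bitwAnd(src, bitwShiftL(1L, ctrl)) != 0L
  dst <- ifelse(on, bitwXor(src, bitwShiftL(1L, tgt)), src)
  U[cbind(dst + 1L, src + 1L)] <- 1
  U
}

# embed a single-qubit unitary on qubit q of an n-qubit register
.embed_1q <- function(u, n, q) {
  U <- matrix(1 + 0i, 1, 1)
  for (k in (n - 1L):0) {
    U <- if (k == q) kronecker(U, u) else kronecker(U, diag(2))
  }
  U
}

.dm_apply_u <- function(rho, U) U %*% rho %*% Conj(t(U))

# k-qubit depolarizing: rho -> (1-p) rho + p I/2^k (x) tr_k rho
.dm_depolarize <- function(rho, n, qubits, p) {
  if (p <= 0) return(rho)
  mix <- rho
  for (q in qubits) {
    acc <- mix
    for (pm in list(c("X"), c("Y"), c("Z"))) {
      u <- switch(pm[[1]],
                  X = matrix(c(0, 1, 1, 0), 2, 2),
                  Y = matrix(c(0, 1i, -1i, 0), 2, 2),
                  Z = diag(c(1, -1)))
      P <- .embed_1q(u, n, q)
      acc <- acc + P %*% mix %*% Conj(t(P))
    }
    mix <- acc / 4
  }
  (1 - p) * rho + p * mix
}

#' Simulate a gate list on a density matrix with noise
#'
#' @param gates gate list (as from [hea_gates()]).
#' @param n_qubits register size.
#' @param noise a `qc_noise_spec` or NULL.
#' @return complex density matrix (2^n x 2^n).
#' @export
simulate_density_matrix <- function(gates, n_qubits, noise = NULL) {
  N <- 2^n_qubits
  rho <- matrix(0+0i, N, N)
  rho[1, 1] <- 1
  for (g in gates) {
    U <- switch(g$type,
      ry = .embed_1q(.u_ry(g$angle), n_qubits, g$qubits[1]),
      rz = .embed_1q(.u_rz(g$angle), n_qubits, g$qubits[1]),
      h = .embed_1q(.u_h, n_qubits, g$qubits[1]),
      sdg = .embed_1q(.u_sdg, n_qubits, g$qubits[1]),
      cx = .u_cx(n_qubits, g$qubits[1], g$qubits[2]),
      stop("unknown gate ", g$type))
    rho <- .dm_apply_u(rho, U)
    if (!is.null(noise)) {
      if (g$type == "cx" && noise$depolarizing_2q > 0) {
        rho <- .dm_depolarize(rho, n_qubits, g$qubits, noise$depolarizing_2q)
      } else if (g$type != "cx" && noise$depolarizing_1q > 0) {
        rho <- .dm_depolarize(rho, n_qubits, g$qubits[1],
                              noise$depolarizing_1q)
      }
    }
  }
  rho
}

# measurement probabilities of one Pauli label on a prepared rho:
# apply the diagonalizing rotations, take the diagonal, apply readout
.pauli_probs <- function(rho, n, codes, noise = NULL) {
  for (q in seq_len(n)) {
    if (codes[q] == 1L) {
      rho <- .dm_apply_u(rho, .embed_1q(.u_h, n, q - 1L))
    } else if (codes[q] == 2L) {
      rho <- .dm_apply_u(rho, .embed_1q(.u_sdg, n, q - 1L))
      rho <- .dm_apply_u(rho, .embed_1q(.u_h, n, q - 1L))
    }
  }
  probs <- pmax(Re(diag(rho)), 0)
  probs <- probs / sum(probs)
  if (!is.null(noise)) {
    ro <- .readout_flips(noise, n)
    if (any(ro$f0 > 0) || any(ro$f1 > 0)) {
      probs <- .apply_flip_channel(probs, n, ro$f0, ro$f1)
    }
  }
  probs
}

#' Noisy shot-sampled expectation values on a prepared circuit
#'
#' Builds the noisy density matrix once, then estimates each requested Pauli
#' label from its own multinomial sample of `noise$shots` shots. Returns a
#' closure usable as an RDM/energy estimator: distinct Pauli labels are
#' sampled once and cached, so operators sharing terms reuse the same counts
#' (as they would in simultaneous readout).
#'
#' @param gates circuit gate list.
#' @param n_qubits register size.
#' @param noise a `qc_noise_spec`.
#' @return `function(op)` estimating the expectation of a `qc_qubit_op`.
#' @export
noisy_estimator <- function(gates, n_qubits, noise) {
  rho <- simulate_density_matrix(gates, n_qubits, noise)
  cache <- new.env(parent = emptyenv())
  identity_label <- strrep("I", n_qubits)
  function(op) {
    codes <- .labels_to_codes(op$labels)
    total <- 0
    for (k in seq_along(op$labels)) {
      lab <- op$labels[k]
      coef <- Re(op$coefs[k])
      if (lab == identity_label) { total <- total + coef; next }
      est <- cache[[lab]]
      if (is.null(est)) {
        ck <- codes[k, ]
        probs <- .pauli_probs(rho, n_qubits, ck, noise)
        support <- which(ck != 0L)
        mask <- as.integer(sum(2^(support - 1L)))
        est <- .sample_z_parity(probs, n_qubits, mask, noise$shots)
        cache[[lab]] <- est
      }
      total <- total + coef * est
    }
    total
  }
}
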