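# VQE: exact and shot-sampled expectation values, SPSA and quasi-Newton
# minimization, RDM measurement.

#' Noise model specification
#'
#' Parameterized noise: single- and two-qubit depolarizing channels (applied
#' after every gate in circuit-level simulations; convention
#' rho -> (1-p) rho + p I/2^k, i.e. p = 1 is fully depolarizing) and a
#' per-qubit readout confusion. A scalar `readout_flip` f gives the symmetric
#' confusion matrix rows (1-f, f) / (f, 1-f).
#'
#' @param depolarizing_1q probability for one-qubit gates.
#' @param depolarizing_2q probability for two-qubit gates.
#' @param readout_flip scalar flip probability, or a list of per-qubit 2x2
#'   confusion matrices (columns: true state; rows: observed).
#' @param shots measurement shots per Pauli term.
#' @return object of class `qc_noise_spec`.
#' @export
noise_spec <- function(depolarizing_1q = 0, depolarizing_2q = 0,
                       readout_flip = 0, shots = 1000L) {
  stopifnot(depolarizing_1q >= 0, depolarizing_1q <= 1,
            depolarizing_2q >= 0, depolarizing_2q <= 1)
  if (is.numeric(readout_flip) && length(readout_flip) == 1L) {
    stopifnot(readout_flip >= 0, readout_flip <= 1)
  }
  structure(list(depolarizing_1q = depolarizing_1q,
                 depolarizing_2q = depolarizing_2q,
                 readout_flip = readout_flip, shots = as.integer(shots)),
            class = "qc_noise_spec")
}

#' Default generic noise point
#'
#' Depolarizing 1e-3 (one-qubit) / 1e-2 (two-qubit), readout flip 2e-2,
#' 1000 shots.
#' @return a `qc_noise_spec`.
#' @export
default_noise <- function() {
  noise_spec(depolarizing_1q = 1e-3, depolarizing_2q = 1e-2,
             readout_flip = 2e-2, shots = 1000L)
}

# rotate a statevector so that the Pauli term becomes Z-diagonal
.rotate_to_z <- function(state, codes) {
  for (q in seq_along(codes)) {
    if (codes[q] == 1L) state <- gate_h(state, q - 1L)
    if (codes[q] == 2L) { state <- gate_sdg(state, q - 1L); state <- gate_h(state, q - 1L) }
  }
  state
}

# apply per-qubit classical bit-flip channels to a probability vector
.apply_flip_channel <- function(probs, n, flip0, flip1 = flip0) {
  for (q in 0:(n - 1L)) {
    p <- .gate_pair_idx(n, q)
    p0 <- probs[p$i0]; p1 <- probs[p$i1]
    f0 <- if (length(flip0) > 1) flip0[q + 1L] else flip0
    f1 <- if (length(flip1) > 1) flip1[q + 1L] else flip1
    probs[p$i0] <- (1 - f0) * p0 + f1 * p1
    probs[p$i1] <- f0 * p0 + (1 - f1) * p1
  }
  probs
}

.readout_flips <- function(noise, n) {
  ro <- noise$readout_flip
  if (is.list(ro)) {
    f0 <- vapply(ro, function(m) m[2, 1], numeric(1))
    f1 <- vapply(ro, function(m) m[1, 2], numeric(1))
    list(f0 = f0, f1 = f1)
  } else {
    list(f0 = rep(ro, n), f1 = rep(ro, n))
  }
}

# sample the +-1 estimator of one Z-diagonal Pauli support
.sample_z_parity <- function(probs, n, support_mask, shots) {
  counts <- as.vector(stats::rmultinom(1, shots, probs))
  outcomes <- 0:(2^n - 1L)
  sign <- (-1)^(.popcount(bitwAnd(outcomes, support_mask)) %% 2L)
  sum(counts * sign) / shots
}

#' Shot-sampled expectation value of a qubit operator
#'
#' Each Pauli term is measured in its own diagonalizing product basis.
#' Without noise this is an unbiased estimator of [expectation()] with
#' standard error ~ shots^(-1/2). Single-qubit depolarizing noise (applied
#' once per qubit before readout) and readout confusion are applied as
#' classical channels on the outcome distribution.
#'
#' @param state a `qc_statevector`.
#' @param op a Hermitian `qc_qubit_op`.
#' @param shots shots per Pauli term (>= 1).
#' @param noise optional `qc_noise_spec` (only `depolarizing_1q` and
#'   `readout_flip` act here; gate noise requires the density-matrix path).
#' @param seed RNG seed.
#' @return estimated expectation value.
#' @export
sampled_expectation <- function(state, op, shots, noise = NULL, seed = 1L) {
  stopifnot(shots >= 1)
  set.seed(seed)
  n <- state$n_qubits
  codes <- .labels_to_codes(op$labels)
  total <- 0
  for (k in seq_along(op$labels)) {
    ck <- codes[k, ]
    support <- which(ck != 0L)
    coef <- Re(op$coefs[k])
    if (length(support) == 0L) { total <- total + coef; next }
    rot <- .rotate_to_z(state, ck)
    probs <- Mod(rot$amps)^2
    probs <- probs / sum(probs)
    if (!is.null(noise)) {
      if (noise$depolarizing_1q > 0) {
        probs <- .apply_flip_channel(probs, n, noise$depolarizing_1q / 2)
      }
      ro <- .readout_flips(noise, n)
      if (any(ro$f0 > 0) || any(ro$f1 > 0)) {
        probs <- .apply_flip_channel(probs, n, ro$f0, ro$f1)
      }
    }
    mask <- as.integer(sum(2^(support - 1L)))
    total <- total + coef * .sample_z_parity(probs, n, mask, shots)
  }
  total
}

#' Optimizer specification for VQE
#'
#' @param method "BFGS" (delegated quasi-Newton with numerical gradient,
#'   for noiseless objectives) or "SPSA" (simultaneous perturbation
#'   stochastic approximation with standard gain sequences
#'   a_k = a/(k+1+A)^alpha, c_k = c/(k+1)^gamma).
#' @param maxit iteration cap.
#' @param a,c,alpha,gamma,A SPSA gain parameters.
#' @param reltol relative tolerance for the deterministic minimizer.
#' @param calibrate calibrate the SPSA learning rate from initial gradient
#'   samples so the first update is ~ `target_step` per parameter.
#' @param target_step calibration target (radians).
#' @return list of class `qc_optimizer_spec`.
#' @export
optimizer_spec <- function(method = c("BFGS", "SPSA"), maxit = NULL,
                           a = 0.1, c = 0.1, alpha = 0.602, gamma = 0.101,
                           A = 10, reltol = 1e-13, calibrate = TRUE,
                           target_step = 0.1) {
  method <- match.arg(method)
  if (is.null(maxit)) maxit <- if (method == "SPSA") 100L else 500L
  structure(list(method = method, maxit = as.integer(maxit), a = a, c = c,
                 alpha = alpha, gamma = gamma, A = A, reltol = reltol,
                 calibrate = calibrate, target_step = target_step),
            class = "qc_optimizer_spec")
}

.spsa_minimize <- function(fn, par, opt) {
  k_dim <- length(par)
  trace <- numeric(opt$maxit)
  a <- opt$a
  if (isTRUE(opt$calibrate)) {
    # standard first-step calibration: choose a so that the initial update
    # magnitude is ~ opt$target_step per parameter
    gmag <- 0
    ncal <- 5L
    for (j in seq_len(ncal)) {
      delta <- sample(c(-1, 1), k_dim, replace = TRUE)
      gmag <- gmag + abs(fn(par + opt$c * delta) - fn(par - opt$c * delta)) /
        (2 * opt$c)
    }
    gmag <- gmag / ncal
    if (gmag > 1e-10) a <- opt$target_step * (opt$A + 1)^opt$alpha / gmag
  }
  for (k in seq_len(opt$maxit)) {
    ak <- a / (k + opt$A)^opt$alpha
    ck <- opt$c / k^opt$gamma
    delta <- sample(c(-1, 1), k_dim, replace = TRUE)
    fp <- fn(par + ck * delta)
    fm <- fn(par - ck * delta)
    ghat <- (fp - fm) / (2 * ck) * (1 / delta)
    par <- par - ak * ghat
    trace[k] <- (fp + fm) / 2
  }
  list(par = par, trace = trace)
}

#' Minimize the energy of an ansatz
#'
#' @param hamiltonian a Hermitian `qc_qubit_op`.
#' @param spec a `qc_ansatz`.
#' @param optimizer an [optimizer_spec()].
#' @param seed seed controlling HEA parameter initialization and SPSA
#'   perturbations.
#' @param evaluator objective override, a `function(params) -> energy`
#'   (used for shot-sampled / noisy objectives); defaults to the exact
#'   statevector expectation.
#' @param init_params starting parameters; default 0 for UCCSD (HF start),
#'   seeded uniform (-pi, pi) for HEA.
#' @param restarts extra seeded starting points for the deterministic
#'   optimizer (local-minimum guard); the best result is kept.
#' @return object of class `qc_vqe_result`: `energy`, `parameters`,
#'   `n_evaluations`, `optimizer_trace` (data.frame iteration/energy),
#'   `converged`.
#' @export
vqe_minimize <- function(hamiltonian, spec,
                         optimizer = optimizer_spec("BFGS"),
                         seed = 1L, evaluator = NULL, init_params = NULL,
                         restarts = 2L) {
  set.seed(seed)
  if (is.null(init_params)) {
    init_params <- if (spec$kind == "UCCSD") rep(0, spec$n_params)
      else stats::runif(spec$n_params, -pi, pi)
  }
  n_eval <- 0L
  energies <- numeric(0)
  obj <- if (is.null(evaluator)) {
    function(p) expectation(ansatz_state(p, spec), hamiltonian)
  } else evaluator
  grad_fn <- if (is.null(evaluator) && spec$kind == "UCCSD") {
    function(p) uccsd_energy_gradient(p, spec, hamiltonian)$gradient
  } else NULL
  fn <- function(p) {
    n_eval <<- n_eval + 1L
    e <- obj(p)
    energies[n_eval] <<- e
    e
  }
  e0 <- fn(init_params)
  converged <- TRUE
  if (spec$n_params == 0L) {
    par <- init_params; e_final <- e0
  } else if (optimizer$method == "BFGS") {
    # seeded multi-start: the primary run starts at init_params (the HF point
    # for UCCSD); extra starts guard against local minima of the ansatz
    # energy landscape
    starts <- list(init_params)
    if (restarts > 0) {
      for (k in seq_len(restarts)) {
        starts[[k + 1L]] <- init_params +
          stats::rnorm(spec$n_params, sd = 0.3)
      }
    }
    best <- NULL
    for (st in starts) {
      res <- stats::optim(st, fn, gr = grad_fn, method = "BFGS",
                          control = list(maxit = optimizer$maxit,
                                         reltol = optimizer$reltol))
      if (is.null(best) || res$value < best$value) best <- res
    }
    res <- best
    par <- res$par; e_final <- res$value
    converged <- res$convergence == 0L
  } else {
    res <- .spsa_minimize(fn, init_params, optimizer)
    par <- res$par
    e_final <- fn(par)
  }
  if (e0 < e_final) { par <- init_params; e_final <- e0 }
  structure(list(
    energy = e_final, parameters = par, n_evaluations = n_eval,
    optimizer_trace = data.frame(iteration = seq_along(energies),
                                 energy = energies),
    converged = converged
  ), class = "qc_vqe_result")
}

#' Construct an RDM pair
#' @param dm1 n x n spin-summed one-body RDM.
#' @param dm2 n^4 spin-summed two-body RDM tensor.
#' @param n_electrons electron count of the underlying state.
#' @param flags processing flags.
#' @return object of class `qc_rdm_pair`.
#' @export
rdm_pair <- function(dm1, dm2, n_electrons,
                     flags = c(normalized = FALSE, symmetrized = FALSE,
                               canonicalized = FALSE)) {
  structure(list(dm1 = dm1, dm2 = dm2, n_electrons = as.integer(n_electrons),
                 flags = flags), class = "qc_rdm_pair")
}

#' Measure spin-summed RDMs of a state
#'
#' Noiseless: exact expectation of every mapped excitation operator. With an
#' `estimator`, each operator expectation is estimated by that function
#' (e.g. a shot-sampling closure), mirroring measurement on hardware.
#'
#' @param state a `qc_statevector`.
#' @param ops output of [rdm_component_operators()].
#' @param estimator optional `function(op) -> value` override.
#' @return a `qc_rdm_pair` (unprocessed flags).
#' @export
measure_rdms <- function(state, ops, estimator = NULL) {
  n <- ops$n_orb
  est <- if (is.null(estimator)) {
    function(op) expectation(state, op)
  } else estimator
  dm1 <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    dm1[p, q] <- est(ops$E[[p]][[q]])
  }
  dm2 <- array(0, c(n, n, n, n))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    for (r in seq_len(n)) for (s in seq_len(n)) {
      dm2[p, q, r, s] <- est(ops$e[[p]][[q]][[r]][[s]])
    }
  }
  rdm_pair(dm1, dm2, n_electrons = round(sum(diag(dm1))))
}
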