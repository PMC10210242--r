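# CASSCF macro-iterations: solve the active-space eigenproblem (exact
# diagonalization or VQE), measure and post-process RDMs, build the
# generalized Fock matrix and first-order orbital gradient, rotate orbitals,
# and repeat to convergence.

#' Convergence criteria for CASSCF
#' @param energy_tol macro-iteration energy change threshold (Hartree).
#' @param gradient_tol orbital gradient norm threshold.
#' @param max_macro macro-iteration cap.
#' @return list of class `qc_convergence`.
#' @export
convergence_criteria <- function(energy_tol = 1e-8, gradient_tol = 1e-5,
                                 max_macro = 200L) {
  stopifnot(energy_tol > 0, gradient_tol > 0, max_macro >= 1)
  structure(list(energy_tol = energy_tol, gradient_tol = gradient_tol,
                 max_macro = as.integer(max_macro)), class = "qc_convergence")
}

#' Frontier active-space MO indices
#'
#' HOMO-centered window: the ceiling(n_elec/2) highest occupied MOs plus
#' enough of the lowest virtuals to reach `n_orb` orbitals.
#'
#' @param scf a `qc_scf`.
#' @param n_elec,n_orb active electron and orbital counts.
#' @return 1-based MO index vector.
#' @export
frontier_indices <- function(scf, n_elec, n_orb) {
  homo <- scf$n_alpha
  n_occ_act <- ceiling(n_elec / 2)
  if (n_occ_act > homo) stop("not enough occupied orbitals")
  first <- homo - n_occ_act + 1L
  idx <- first:(first + n_orb - 1L)
  if (max(idx) > scf$n_mo) stop("not enough virtual orbitals")
  as.integer(idx)
}

# inactive Fock matrix in the full MO basis
.inactive_fock <- function(mo, ia) {
  Fi <- mo$h
  if (length(ia)) {
    Fi <- Fi + 2 * apply(mo$g[, , ia, ia, drop = FALSE], c(1, 2),
                         function(m) sum(diag(as.matrix(m)))) -
      apply(mo$g[, ia, ia, , drop = FALSE], c(1, 4),
            function(m) sum(diag(as.matrix(m))))
  }
  (Fi + t(Fi)) / 2
}

# active Fock matrix: Fa_pq = sum_vw dm1[v,w] (g[p,q,v,w] - g[p,w,v,q]/2)
.active_fock <- function(mo, aa, dm1) {
  n <- nrow(mo$h)
  Fa <- matrix(0, n, n)
  for (v in seq_along(aa)) for (w in seq_along(aa)) {
    dvw <- dm1[v, w]
    if (dvw == 0) next
    Fa <- Fa + dvw * (mo$g[, , aa[v], aa[w]] - 0.5 * mo$g[, aa[w], aa[v], ])
  }
  Fa
}

#' Generalized Fock matrix
#'
#' F[m, q] = sum_p D1[m, p] h[q, p] + sum_{prs} d2[m, p, r, s] g[q, p, r, s]
#' with the full-space RDMs (inactive block of D1 equal to 2 I). Computed in
#' blocked form: inactive rows 2 (Fi + Fa), active rows dm1 . Fi + Q with
#' Q[v, q] = sum_{wxy} dm2[v, w, x, y] g[q, w, x, y], virtual rows zero.
#'
#' @param mo [mo_integrals()] output (full MO basis).
#' @param rdms processed `qc_rdm_pair` (active space).
#' @param act a `qc_active_space`.
#' @return n_mo x n_mo matrix.
#' @export
generalized_fock <- function(mo, rdms, act) {
  n <- nrow(mo$h)
  ia <- act$inactive_indices
  aa <- act$active_indices
  Fi <- .inactive_fock(mo, ia)
  Fa <- .active_fock(mo, aa, rdms$dm1)
  F <- matrix(0, n, n)
  if (length(ia)) F[ia, ] <- 2 * (Fi + Fa)[ia, ]
  if (length(aa)) {
    F[aa, ] <- rdms$dm1 %*% t(Fi[, aa, drop = FALSE])
    na <- length(aa)
    g_act_full <- mo$g[, aa, aa, aa, drop = FALSE] # [q, w, x, y]
    gq <- matrix(g_act_full, n, na^3)              # q x (w,x,y)
    for (vi in seq_len(na)) {
      dv <- as.vector(rdms$dm2[vi, , , ])
      F[aa[vi], ] <- F[aa[vi], ] + as.vector(gq %*% dv)
    }
  }
  F
}

# non-redundant rotation pairs (p < q style, stored as matrix rows)
.rotation_pairs <- function(act, n_mo) {
  ia <- act$inactive_indices
  aa <- act$active_indices
  va <- act$virtual_indices
  pairs <- rbind(
    if (length(ia) && length(aa)) expand.grid(p = ia, q = aa),
    if (length(ia) && length(va)) expand.grid(p = ia, q = va),
    if (length(aa) && length(va)) expand.grid(p = aa, q = va)
  )
  as.matrix(pairs)
}

#' Orbital gradient over non-redundant rotations
#'
#' g_pq = 2 (F_pq - F_qp) restricted to inactive-active, inactive-virtual and
#' active-virtual pairs (active-active rotations are redundant and fixed by
#' canonicalization instead).
#'
#' @param F generalized Fock matrix.
#' @param act a `qc_active_space`.
#' @param n_mo number of MOs.
#' @return list: `grad` (vector over pairs), `pairs` (index matrix).
#' @export
orbital_gradient <- function(F, act, n_mo = nrow(F)) {
  pairs <- .rotation_pairs(act, n_mo)
  grad <- 2 * (F[pairs] - F[pairs[, c(2, 1), drop = FALSE]])
  list(grad = grad, pairs = pairs)
}

# exponential of a real antisymmetric matrix (orthogonal result)
.expm_skew <- function(K) {
  H <- -1i * K
  ev <- eigen((H + Conj(t(H))) / 2)
  Re(ev$vectors %*% (exp(1i * ev$values) * Conj(t(ev$vectors))))
}

#' Rotate MO coefficients
#'
#' C <- C exp(-kappa), kappa antisymmetric with kappa[p, q] = step over the
#' non-redundant pairs; with this sign the directional derivative of the
#' energy along `step` equals the [orbital_gradient()] vector. Orthonormality
#' under the overlap metric is preserved exactly (up to roundoff).
#'
#' @param C MO coefficient matrix.
#' @param step vector indexed like the gradient pairs.
#' @param pairs pair index matrix from [orbital_gradient()].
#' @return rotated coefficient matrix.
#' @export
rotate_orbitals <- function(C, step, pairs) {
  n <- ncol(C)
  K <- matrix(0, n, n)
  K[pairs] <- step
  K <- K - t(K)
  C %*% .expm_skew(-K)
}

# diagonal Hessian approximation for the rotation pairs
.diag_hessian <- function(Fi, Fa, Fgen, rdms, act, pairs) {
  n <- nrow(Fi)
  d1tot <- numeric(n)
  d1tot[act$inactive_indices] <- 2
  d1tot[act$active_indices] <- diag(rdms$dm1)
  Fc <- Fi + Fa
  h <- 2 * (d1tot[pairs[, 1]] * diag(Fc)[pairs[, 2]] +
              d1tot[pairs[, 2]] * diag(Fc)[pairs[, 1]]) -
    2 * (diag(Fgen)[pairs[, 1]] + diag(Fgen)[pairs[, 2]])
  pmax(h, 0.05)
}

# Inner orbital relaxation at frozen RDMs: preconditioned steepest descent
# with a quadratic-interpolation line search on the frozen-RDM energy
# E(C') = e_core(C') + sum h_eff dm1 + 1/2 sum g_act dm2.
.relax_orbitals <- function(ints, C, act, rdms, og0, mo0,
                            gradient_tol = 1e-5, max_rotation = 0.2,
                            max_inner = 20L) {
  pairs <- og0$pairs
  surrogate <- function(Cx) {
    active_energy(build_active_hamiltonian(ints, Cx, act), rdms)
  }
  e_cur <- active_energy(build_active_hamiltonian(ints, C, act, mo = mo0),
                         rdms)
  g <- og0$grad
  g0norm <- sqrt(sum(g^2))
  mo <- mo0
  for (inner in seq_len(max_inner)) {
    gnorm <- sqrt(sum(g^2))
    if (gnorm < max(gradient_tol / 4, 0.02 * g0norm)) break
    Fi <- .inactive_fock(mo, act$inactive_indices)
    Fa <- .active_fock(mo, act$active_indices, rdms$dm1)
    Fgen <- generalized_fock(mo, rdms, act)
    hd <- .diag_hessian(Fi, Fa, Fgen, rdms, act, pairs)
    d <- -g / hd
    mx <- max(abs(d))
    if (mx > max_rotation) d <- d * (max_rotation / mx)
    slope <- sum(g * d) # dE/dt at t = 0, negative for a descent direction
    if (slope >= 0) { d <- -g; slope <- -sum(g * g) }
    t1 <- 1
    accepted <- FALSE
    for (ls in 1:8) {
      C_try <- rotate_orbitals(C, t1 * d, pairs)
      e_try <- surrogate(C_try)
      if (e_try <= e_cur + 1e-13) {
        # quadratic interpolation for a better step
        denom <- e_try - e_cur - slope * t1
        if (denom > 0) {
          t_opt <- -slope * t1^2 / (2 * denom)
          if (t_opt > 0 && abs(t_opt - t1) > 0.1 * t1 &&
              t_opt < 4 * t1) {
            C_opt <- rotate_orbitals(C, t_opt * d, pairs)
            e_opt <- surrogate(C_opt)
            if (e_opt < e_try) { C_try <- C_opt; e_try <- e_opt }
          }
        }
        C <- C_try
        e_cur <- e_try
        accepted <- TRUE
        break
      }
      t1 <- t1 / 4
    }
    if (!accepted) break
    mo <- mo_integrals(ints, C)
    Fgen <- generalized_fock(mo, rdms, act)
    g <- orbital_gradient(Fgen, act)$grad
  }
  C
}

# solve the active-space problem with the selected driver
.solve_active <- function(h_act, driver, encoding, sector, vqe_opts, warm) {
  if (driver == "FCI") {
    qh <- qubit_hamiltonian(h_act, encoding, sz2 = sector$sz2)
    gs <- ground_state(qh, list(n_electrons = sector$n_electrons,
                                sz2 = sector$sz2),
                       h_act$n_active_orbitals, encoding)
    ops <- rdm_component_operators(h_act$n_active_orbitals, encoding,
                                   n_elec = sector$n_electrons,
                                   sz2 = sector$sz2)
    rdms <- measure_rdms(gs$state, ops)
    return(list(energy = gs$energy, rdms = rdms, warm = warm))
  }
  qh <- qubit_hamiltonian(h_act, encoding, sz2 = sector$sz2)
  n_alpha <- (sector$n_electrons + sector$sz2) %/% 2L
  n_beta <- (sector$n_electrons - sector$sz2) %/% 2L
  if (driver == "UCCSD-VQE") {
    spec <- warm$spec
    if (is.null(spec)) {
      spec <- uccsd_spec(h_act$n_active_orbitals, n_alpha, n_beta, encoding)
    }
    init <- if (!is.null(warm$params)) warm$params else NULL
    res <- vqe_minimize(qh, spec, optimizer = vqe_opts$optimizer,
                        seed = vqe_opts$seed, init_params = init,
                        restarts = if (is.null(init)) 2L else 0L)
  } else if (driver == "HEA-VQE") {
    spec <- warm$spec
    if (is.null(spec)) {
      spec <- hea_spec(qh$n_qubits, n_layers = vqe_opts$hea_layers)
    }
    init <- if (!is.null(warm$params)) warm$params else NULL
    evaluator <- if (!is.null(vqe_opts$make_evaluator)) {
      vqe_opts$make_evaluator(qh, spec)
    } else NULL
    res <- vqe_minimize(qh, spec, optimizer = vqe_opts$optimizer,
                        seed = vqe_opts$seed, evaluator = evaluator,
                        init_params = init)
  } else stop("unknown driver: ", driver)
  state <- ansatz_state(res$parameters, spec)
  ops <- rdm_component_operators(h_act$n_active_orbitals, encoding,
                                 n_elec = sector$n_electrons,
                                 sz2 = sector$sz2)
  estimator <- if (!is.null(vqe_opts$make_rdm_estimator)) {
    vqe_opts$make_rdm_estimator(res$parameters, spec)
  } else NULL
  rdms <- measure_rdms(state, ops, estimator = estimator)
  energy <- if (!is.null(vqe_opts$make_evaluator)) res$energy else
    expectation(state, qh)
  list(energy = energy, rdms = rdms,
       warm = list(spec = spec, params = res$parameters))
}

#' Run a CASSCF calculation
#'
#' Two-step CASSCF: alternate the active-space solve (exact diagonalization,
#' UCCSD-VQE, or HEA-VQE) with a first-order orbital update (generalized-Fock
#' gradient, diagonal Hessian, trust-radius damping). Convergence requires
#' the energy change below `crit$energy_tol` and (for noiseless drivers) the
#' gradient norm below `crit$gradient_tol`.
#'
#' @param ints a `qc_ao_integrals` (or pass `geom` and `basis`).
#' @param act_spec list with `n_elec` and either `indices` (1-based MO list)
#'   or `n_orb` (frontier window).
#' @param driver "FCI", "UCCSD-VQE" or "HEA-VQE".
#' @param crit a [convergence_criteria()].
#' @param encoding "jw" or "parity".
#' @param canonical canonicalize active orbitals to natural orbitals each
#'   macro-iteration (default TRUE).
#' @param scf optional precomputed `qc_scf`; also accepts a coefficient
#'   matrix via `initial_coefficients` for warm starts.
#' @param initial_coefficients optional starting MO coefficient matrix.
#' @param vqe_opts list: `optimizer` ([optimizer_spec()]), `seed`,
#'   `hea_layers`, and optional `make_evaluator(h, spec)` /
#'   `make_rdm_estimator(params, spec)` factories for noisy objectives.
#' @param noisy treat the driver as noisy: convergence on energy change only,
#'   occupation clipping enabled.
#' @param max_rotation trust radius: largest |kappa| element per step (rad).
#' @param verbose print per-iteration energies.
#' @return list of class `qc_casscf`: `energy`, `mo_coefficients`,
#'   `occupations`, `rdms`, `converged`, `macro_iterations`, `trace`
#'   (data.frame: macro_iteration, energy, gradient_norm, occupations...),
#'   `active_space`, `warm` (driver warm-start data).
#' @export
run_casscf <- function(ints, act_spec, driver = c("FCI", "UCCSD-VQE", "HEA-VQE"),
                       crit = convergence_criteria(),
                       encoding = c("jw", "parity"),
                       canonical = TRUE, scf = NULL,
                       initial_coefficients = NULL,
                       vqe_opts = list(), noisy = FALSE,
                       max_rotation = 0.2, verbose = FALSE) {
  driver <- match.arg(driver)
  encoding <- match.arg(encoding)
  if (is.null(vqe_opts$optimizer)) {
    vqe_opts$optimizer <- optimizer_spec(if (noisy) "SPSA" else "BFGS")
  }
  if (is.null(vqe_opts$seed)) vqe_opts$seed <- 1L
  if (is.null(vqe_opts$hea_layers)) vqe_opts$hea_layers <- 1L
  if (is.null(scf)) scf <- run_hf(ints)
  act <- if (!is.null(act_spec$indices)) {
    select_active_space(scf, act_spec$n_elec, act_spec$indices)
  } else {
    select_active_space(scf, act_spec$n_elec,
                        frontier_indices(scf, act_spec$n_elec, act_spec$n_orb))
  }
  sector <- list(n_electrons = act$n_active_electrons, sz2 = act$sz2)
  C <- if (!is.null(initial_coefficients)) initial_coefficients else
    scf$mo_coefficients
  n_mo <- ncol(C)
  aa <- act$active_indices
  warm <- list()
  e_prev <- Inf
  converged <- FALSE
  trace <- list()
  energy <- NA_real_
  gnorm <- NA_real_
  rdms <- NULL
  occ <- NULL

  for (macro in seq_len(crit$max_macro)) {
    mo <- mo_integrals(ints, C)
    h_act <- build_active_hamiltonian(ints, C, act, mo = mo)
    vqe_opts_macro <- vqe_opts
    vqe_opts_macro$seed <- vqe_opts$seed + 101L * (macro - 1L)
    sol <- .solve_active(h_act, driver, encoding, sector, vqe_opts_macro, warm)
    warm <- sol$warm
    energy <- sol$energy

    proc <- process_rdms(sol$rdms, canonical = canonical, clip = noisy)
    rdms <- proc$rdms
    occ <- proc$transform$occupations
    if (canonical) {
      C[, aa] <- C[, aa, drop = FALSE] %*% proc$transform$rotation
      mo <- mo_integrals(ints, C)
    }
    Fgen <- generalized_fock(mo, rdms, act)
    og <- orbital_gradient(Fgen, act, n_mo)
    gnorm <- sqrt(sum(og$grad^2))
    de <- energy - e_prev

    trace_row <- data.frame(macro_iteration = macro, energy = energy,
                            gradient_norm = gnorm)
    if (verbose) {
      message(sprintf("macro %3d  E = %.10f  |g| = %.3e  dE = %.3e",
                      macro, energy, gnorm, de))
    }
    trace[[length(trace) + 1L]] <- trace_row

    if (abs(de) < crit$energy_tol && (noisy || gnorm < crit$gradient_tol)) {
      converged <- TRUE
      break
    }
    e_prev <- energy

    # inner orbital relaxation on the frozen-RDM energy surrogate: the CI
    # re-solve at the new orbitals can only lower it, so each macro-iteration
    # decreases the true energy monotonically (noiseless drivers)
    C <- .relax_orbitals(ints, C, act, rdms, og, mo,
                         gradient_tol = crit$gradient_tol,
                         max_rotation = max_rotation)
  }

  structure(list(
    energy = energy, mo_coefficients = C, occupations = occ, rdms = rdms,
    converged = converged, macro_iterations = length(trace),
    trace = do.call(rbind, trace), active_space = act,
    gradient_norm = gnorm, warm = warm, scf = scf
  ), class = "qc_casscf")
}

#' Warm-start a CASSCF from a smaller converged active space
#'
#' @param small a converged `qc_casscf`.
#' @param ints AO integrals of the same molecule/basis.
#' @param act_spec active-space spec of the larger run; its indices must
#'   contain the smaller run's active indices.
#' @param ... passed to [run_casscf()].
#' @return a `qc_casscf`.
#' @export
warm_start <- function(small, ints, act_spec, ...) {
  if (!is.null(act_spec$indices) &&
      !all(small$active_space$active_indices %in% act_spec$indices)) {
    stop("the larger active space must contain the smaller one")
  }
  run_casscf(ints, act_spec, scf = small$scf,
             initial_coefficients = small$mo_coefficients, ...)
}

#' @export
print.qc_casscf <- function(x, ...) {
  cat(sprintf("CASSCF: E = %.9f Ha after %d macro-iterations (converged = %s)\n",
              x$energy, x$macro_iterations, x$converged))
  if (!is.null(x$occupations)) {
    cat("  natural occupations:",
        paste(sprintf("%.3f", x$occupations), collapse = " "), "\n")
  }
  invisible(x)
}
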