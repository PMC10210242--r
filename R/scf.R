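# Restricted (RHF) and restricted open-shell (ROHF) Hartree-Fock with DIIS.

.build_jk <- function(eri, D) {
  n <- nrow(D)
  g2 <- matrix(eri, n * n, n * n)     # (pq) x (rs), chemists' (pq|rs)
  J <- matrix(g2 %*% as.vector(D), n, n)
  # K[p,q] = sum_{r,s} D[r,s] * (pr|sq) = sum eri[p,r,s,q] D[r,s]
  gK <- aperm(eri, c(1, 4, 2, 3))     # gK[p,q,r,s] = eri[p,r,s,q]
  K <- matrix(matrix(gK, n * n, n * n) %*% as.vector(D), n, n)
  list(J = J, K = K)
}

.diis_extrapolate <- function(fock_list, err_list) {
  m <- length(fock_list)
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B[i, j] <- sum(err_list[[i]] * err_list[[j]])
  }
  B[m + 1, seq_len(m)] <- -1
  B[seq_len(m), m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  c_sol <- tryCatch(solve(B, rhs), error = function(e) NULL)
  if (is.null(c_sol)) return(fock_list[[m]])
  Reduce(`+`, Map(`*`, fock_list, c_sol[seq_len(m)]))
}

#' Run a Hartree-Fock calculation
#'
#' Closed-shell systems use RHF; open-shell systems (multiplicity > 1) use
#' ROHF with a Guest-Saunders effective Fock matrix. Convergence requires an
#' energy change below `e_tol` and a DIIS residual below `d_tol`.
#'
#' @param ints a `qc_ao_integrals`.
#' @param e_tol energy convergence threshold (Hartree).
#' @param d_tol DIIS residual threshold.
#' @param max_cycles maximum SCF cycles.
#' @return object of class `qc_scf`: `mo_coefficients`, `mo_energies`,
#'   `hf_energy`, `occupations`, `converged`, `n_alpha`, `n_beta`.
#' @export
run_hf <- function(ints, e_tol = 1e-10, d_tol = 1e-8, max_cycles = 200L) {
  geom <- ints$geometry
  n_elec <- geom$n_electrons
  mult <- geom$multiplicity
  n_open <- mult - 1L
  if ((n_elec - n_open) %% 2L != 0L) stop("electron/multiplicity mismatch")
  n_beta <- (n_elec - n_open) %/% 2L
  n_alpha <- n_beta + n_open
  S <- ints$overlap
  H <- ints$core_hamiltonian
  n <- ints$n_basis
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)

  solve_fock <- function(F) {
    Fp <- crossprod(X, F %*% X)
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)  # ascending orbital energies
    list(C = X %*% ef$vectors[, ord, drop = FALSE], e = ef$values[ord])
  }

  sol <- solve_fock(H)
  C <- sol$C
  e_old <- Inf
  converged <- FALSE
  fock_hist <- list(); err_hist <- list()
  energy <- NA_real_
  mo_e <- sol$e
  resid <- Inf

  for (cycle in seq_len(max_cycles)) {
    Ca <- C[, seq_len(n_alpha), drop = FALSE]
    Cb <- C[, seq_len(n_beta), drop = FALSE]
    Da <- tcrossprod(Ca)
    Db <- tcrossprod(Cb)
    Dt <- Da + Db
    jka <- .build_jk(ints$eri, Dt)
    Ka <- .build_jk(ints$eri, Da)$K
    Kb <- if (n_beta > 0) .build_jk(ints$eri, Db)$K else matrix(0, n, n)
    Fa <- H + jka$J - Ka
    Fb <- H + jka$J - Kb
    energy <- 0.5 * sum(Da * (H + Fa)) + 0.5 * sum(Db * (H + Fb)) +
      ints$nuclear_repulsion

    if (n_open == 0L) {
      F_eff <- Fa
    } else {
      # Guest-Saunders coupling in the current MO basis
      Fa_mo <- crossprod(C, Fa %*% C)
      Fb_mo <- crossprod(C, Fb %*% C)
      docc <- seq_len(n_beta)
      socc <- if (n_open > 0) (n_beta + 1L):n_alpha else integer(0)
      virt <- setdiff(seq_len(n), c(docc, socc))
      Fe <- (Fa_mo + Fb_mo) / 2
      Fe[docc, socc] <- Fb_mo[docc, socc]; Fe[socc, docc] <- Fb_mo[socc, docc]
      Fe[socc, virt] <- Fa_mo[socc, virt]; Fe[virt, socc] <- Fa_mo[virt, socc]
      SC <- S %*% C
      F_eff <- SC %*% Fe %*% t(SC)
    }

    err <- F_eff %*% (if (n_open == 0L) Da else (Da + Db) / 2) %*% S -
      S %*% (if (n_open == 0L) Da else (Da + Db) / 2) %*% F_eff
    err <- crossprod(X, err %*% X)
    resid <- max(abs(err))
    fock_hist <- c(fock_hist, list(F_eff))
    err_hist <- c(err_hist, list(err))
    if (length(fock_hist) > 8) {
      fock_hist <- fock_hist[-1]; err_hist <- err_hist[-1]
    }
    if (abs(energy - e_old) < e_tol && resid < d_tol) {
      converged <- TRUE
      sol <- solve_fock(F_eff)
      C <- sol$C; mo_e <- sol$e
      break
    }
    e_old <- energy
    F_use <- if (length(fock_hist) >= 2) {
      .diis_extrapolate(fock_hist, err_hist)
    } else F_eff
    sol <- solve_fock(F_use)
    C <- sol$C; mo_e <- sol$e
  }
  if (!converged) {
    stop(sprintf("SCF failed to converge in %d cycles (last E = %.10f, residual %.2e)",
                 max_cycles, energy, resid))
  }
  occ <- numeric(n)
  occ[seq_len(n_beta)] <- 2
  if (n_open > 0) occ[(n_beta + 1L):n_alpha] <- 1
  structure(list(
    mo_coefficients = C, mo_energies = mo_e, hf_energy = energy,
    occupations = occ, converged = converged,
    n_alpha = n_alpha, n_beta = n_beta, n_mo = n
  ), class = "qc_scf")
}

#' @export
print.qc_scf <- function(x, ...) {
  cat(sprintf("SCF: E = %.10f Ha, converged = %s, n_mo = %d (%d alpha / %d beta)\n",
              x$hf_energy, x$converged, x$n_mo, x$n_alpha, x$n_beta))
  invisible(x)
}
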