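test_that("the analytic orbital gradient matches central finite differences", {
  ints <- water_ints(); scf <- water_scf()
  act <- select_active_space(scf, 2L, c(scf$n_alpha, scf$n_alpha + 1L))
  C <- scf$mo_coefficients
  mo <- mo_integrals(ints, C)
  ha <- build_active_hamiltonian(ints, C, act, mo = mo)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(2, "jw"))
  rdms <- process_rdms(rd, canonical = FALSE)$rdms
  og <- orbital_gradient(generalized_fock(mo, rdms, act), act)
  efun <- function(v) {
    active_energy(build_active_hamiltonian(
      ints, rotate_orbitals(C, v, og$pairs), act), rdms)
  }
  eps <- 1e-6
  fd <- vapply(seq_along(og$grad), function(k) {
    v <- numeric(length(og$grad)); v[k] <- eps
    (efun(v) - efun(-v)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(og$grad - fd)), 1e-6)
})

test_that("a symmetric generalized Fock matrix gives a zero gradient", {
  scf <- water_scf()
  act <- select_active_space(scf, 2L, c(scf$n_alpha, scf$n_alpha + 1L))
  F <- diag(7) + 0.5
  expect_equal(orbital_gradient(F, act, 7)$grad,
               rep(0, length(qcasscf:::.rotation_pairs(act, 7)) / 2))
})

test_that("Brillouin condition: occupied-virtual gradient vanishes at HF", {
  ints <- water_ints(); scf <- water_scf()
  act <- select_active_space(scf, 2L, c(scf$n_alpha, scf$n_alpha + 1L))
  mo <- mo_integrals(ints, scf$mo_coefficients)
  # HF-determinant RDMs in the active space: HOMO doubly occupied
  dm1 <- diag(c(2, 0))
  dm2 <- array(0, rep(2, 4)); dm2[1, 1, 1, 1] <- 2
  rdms <- rdm_pair(dm1, dm2, 2)
  og <- orbital_gradient(generalized_fock(mo, rdms, act), act)
  expect_lt(max(abs(og$grad)), 1e-7)
})

test_that("orbital rotations preserve overlap-metric orthonormality", {
  ints <- water_ints(); scf <- water_scf()
  act <- select_active_space(scf, 2L, c(scf$n_alpha, scf$n_alpha + 1L))
  pairs <- qcasscf:::.rotation_pairs(act, 7)
  C0 <- scf$mo_coefficients
  expect_equal(rotate_orbitals(C0, rep(0, nrow(pairs)), pairs), C0)
  set.seed(61)
  C1 <- rotate_orbitals(C0, rnorm(nrow(pairs), sd = 0.3), pairs)
  expect_equal(t(C1) %*% ints$overlap %*% C1, diag(7), tolerance = 1e-10)
})

test_that("CASSCF converges below CASCI with a monotone energy trace", {
  ints <- water_ints(); scf <- water_scf()
  spec <- list(n_elec = 2, n_orb = 2)
  act <- select_active_space(scf, 2L, frontier_indices(scf, 2, 2))
  e_casci <- fci_solve(build_active_hamiltonian(ints, scf, act))$energy
  res <- run_casscf(ints, spec, driver = "FCI", scf = scf)
  expect_true(res$converged)
  expect_lt(res$energy, e_casci)
  expect_lt(res$gradient_norm, 1e-5)
  expect_true(all(diff(res$trace$energy) < 1e-9))
})

test_that("UCCSD-VQE and FCI drivers agree for CAS(2,2)", {
  ints <- water_ints(); scf <- water_scf()
  spec <- list(n_elec = 2, n_orb = 2)
  e_fci <- run_casscf(ints, spec, driver = "FCI", scf = scf)$energy
  e_vqe <- run_casscf(ints, spec, driver = "UCCSD-VQE", scf = scf)$energy
  expect_equal(e_vqe, e_fci, tolerance = 1e-6)
})

test_that("noiseless canonical and noncanonical runs converge identically", {
  ints <- water_ints(); scf <- water_scf()
  spec <- list(n_elec = 2, n_orb = 2)
  e_c <- run_casscf(ints, spec, driver = "FCI", scf = scf, canonical = TRUE)
  e_n <- run_casscf(ints, spec, driver = "FCI", scf = scf, canonical = FALSE)
  expect_equal(e_c$energy, e_n$energy, tolerance = 1e-8)
})

test_that("the converged energy is invariant to initial active rotations", {
  ints <- water_ints(); scf <- water_scf()
  spec <- list(n_elec = 2, n_orb = 2)
  res0 <- run_casscf(ints, spec, driver = "FCI", scf = scf)
  act <- select_active_space(scf, 2L, frontier_indices(scf, 2, 2))
  th <- 0.7
  U <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  C <- scf$mo_coefficients
  C[, act$active_indices] <- C[, act$active_indices] %*% U
  res1 <- run_casscf(ints, spec, driver = "FCI", scf = scf,
                     initial_coefficients = C)
  expect_equal(res1$energy, res0$energy, tolerance = 1e-8)
})

test_that("warm starts reuse converged orbitals and converge immediately", {
  ints <- water_ints(); scf <- water_scf()
  scf <- water_scf()
  res22 <- run_casscf(ints, list(n_elec = 2,
                                 indices = c(scf$n_alpha - 1L, scf$n_alpha + 1L)),
                      driver = "FCI", scf = scf)
  # warm start from itself: converged on the second macro-iteration
  again <- warm_start(res22, ints,
                      list(n_elec = 2,
                           indices = c(scf$n_alpha - 1L, scf$n_alpha + 1L)),
                      driver = "FCI")
  expect_lte(again$macro_iterations, 2)
  expect_equal(again$energy, res22$energy, tolerance = 1e-9)
  # enlarging the active space from the converged small one
  idx44 <- c(scf$n_alpha - 2L, scf$n_alpha - 1L, scf$n_alpha + 1L,
             scf$n_alpha + 2L)
  warm <- warm_start(res22, ints, list(n_elec = 4, indices = idx44),
                     driver = "FCI")
  cold <- run_casscf(ints, list(n_elec = 4, indices = idx44),
                     driver = "FCI", scf = scf)
  expect_true(warm$converged)
  expect_equal(warm$energy, cold$energy, tolerance = 1e-8)
  expect_error(warm_start(res22, ints, list(n_elec = 2, indices = c(1L, 2L))),
               "must contain")
})
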