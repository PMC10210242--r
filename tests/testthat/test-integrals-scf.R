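test_that("contracted basis-function counts match the standard sets", {
  w <- water_geometry()
  expect_equal(count_basis_functions(w, "sto-3g"), 7)
  expect_equal(count_basis_functions(w, "6-31g"), 13)
  expect_equal(count_basis_functions(w, "cc-pvdz"), 24)
  expect_equal(count_basis_functions(h2_geometry(), "sto-3g"), 2)
})

test_that("unknown basis or element raises a configuration error", {
  expect_error(compute_ao_integrals(h2_geometry(), "no-such-basis"),
               "unknown basis")
  g <- geometry(c("Ne"), matrix(0, 1, 3))
  expect_error(compute_ao_integrals(g, "cc-pvdz"), "no data for element")
})

test_that("AO integrals have the required structure", {
  ints <- water_ints()
  S <- ints$overlap
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
  expect_equal(ints$core_hamiltonian, t(ints$core_hamiltonian),
               tolerance = 1e-10)
  g <- ints$eri
  # spot-check the 8-fold permutational symmetry
  set.seed(1)
  for (k in 1:20) {
    ix <- sample(ints$n_basis, 4, replace = TRUE)
    expect_equal(g[ix[1], ix[2], ix[3], ix[4]], g[ix[2], ix[1], ix[3], ix[4]])
    expect_equal(g[ix[1], ix[2], ix[3], ix[4]], g[ix[3], ix[4], ix[1], ix[2]])
    expect_equal(g[ix[1], ix[2], ix[3], ix[4]], g[ix[2], ix[1], ix[4], ix[3]])
  }
})

test_that("H2/STO-3G HF matches an independent textbook Roothaan oracle", {
  ints <- compute_ao_integrals(h2_geometry(0.74), "sto-3g")
  scf <- run_hf(ints)
  # independent oracle: plain fixed-point Roothaan iteration, no DIIS,
  # written against the raw integral arrays
  S <- ints$overlap; H <- ints$core_hamiltonian; g <- ints$eri
  X <- with(eigen(S, symmetric = TRUE),
            vectors %*% diag(1 / sqrt(values)) %*% t(vectors))
  C <- NULL; D <- matrix(0, 2, 2); e_old <- 0
  for (it in 1:500) {
    F <- H
    for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
      F[p, q] <- F[p, q] + D[r, s] * (g[p, q, r, s] - 0.5 * g[p, r, s, q])
    }
    e <- 0.5 * sum(D * (H + F)) + ints$nuclear_repulsion
    Fp <- t(X) %*% F %*% X
    ev <- eigen(Fp, symmetric = TRUE)
    C <- X %*% ev$vectors[, order(ev$values), drop = FALSE]
    D <- 2 * tcrossprod(C[, 1, drop = FALSE])
    if (abs(e - e_old) < 1e-12 && it > 3) break
    e_old <- e
  }
  expect_equal(scf$hf_energy, e, tolerance = 1e-8)
  expect_true(scf$converged)
})

test_that("one-electron systems reduce HF to the core-Hamiltonian eigenvalue", {
  g <- parse_xyz("1\nH atom\nH 0 0 0", multiplicity = 2)
  ints <- compute_ao_integrals(g, "sto-3g")
  scf <- run_hf(ints)
  expect_equal(scf$hf_energy,
               min(eigen(ints$core_hamiltonian, symmetric = TRUE,
                         only.values = TRUE)$values),
               tolerance = 1e-10)
})

test_that("MO coefficients are orthonormal under the overlap metric", {
  scf <- water_scf()
  S <- water_ints()$overlap
  gram <- t(scf$mo_coefficients) %*% S %*% scf$mo_coefficients
  expect_equal(gram, diag(scf$n_mo), tolerance = 1e-8)
  expect_equal(scf$n_mo, 7) # n_mo = n_basis
})

test_that("HF is variational: above the exact full-space ground state", {
  # H2/STO-3G full space is a CAS(2,2): FCI lies below HF
  ints <- compute_ao_integrals(h2_geometry(0.74), "sto-3g")
  scf <- run_hf(ints)
  act <- select_active_space(scf, 2L, 1:2)
  gs <- fci_solve(build_active_hamiltonian(ints, scf, act))
  expect_true(scf$hf_energy >= gs$energy)
})
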