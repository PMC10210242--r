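test_that("active-space bookkeeping: inactive = lowest occupied not selected", {
  scf <- water_scf()
  homo <- scf$n_alpha
  idx <- c(homo - 2L, homo - 1L, homo + 1L, homo + 2L) # skip the HOMO
  act <- select_active_space(scf, 4L, idx)
  expect_length(act$inactive_indices, 3)
  expect_true(homo %in% act$inactive_indices)
  expect_setequal(c(act$inactive_indices, act$active_indices,
                    act$virtual_indices), seq_len(scf$n_mo))

  act2 <- select_active_space(scf, 2L, c(homo - 1L, homo + 1L))
  expect_length(act2$inactive_indices, 4)
  expect_true(homo %in% act2$inactive_indices)
})

test_that("full-space active selection leaves no inactive orbitals", {
  scf <- water_scf()
  act <- select_active_space(scf, 10L, 1:7)
  expect_length(act$inactive_indices, 0)
  expect_length(act$virtual_indices, 0)
})

test_that("impossible electron bookkeeping is a specification error", {
  scf <- water_scf()
  expect_error(select_active_space(scf, 3L, 5:6), "closed shell")
  expect_error(select_active_space(scf, 5L, 5:6), "\\[0, 2")
  expect_error(select_active_space(scf, 2L, c(5, 99)), "out of range")
})

test_that("empty active space reduces e_core to the HF energy", {
  ints <- water_ints(); scf <- water_scf()
  act <- select_active_space(scf, 0L, integer(0))
  ha <- build_active_hamiltonian(ints, scf, act)
  expect_equal(dim(ha$h_eff), c(0L, 0L))
  expect_equal(ha$e_core, scf$hf_energy, tolerance = 1e-10)
})

test_that("doubly occupied determinant energy from h_eff/g_act matches HF", {
  # CAS(2,1) on the HOMO: the closed-shell determinant has dm1 = 2,
  # dm2[1,1,1,1] = 2, so E = e_core + 2 h_eff + g_act[1,1,1,1]
  ints <- water_ints(); scf <- water_scf()
  act <- select_active_space(scf, 2L, scf$n_alpha)
  ha <- build_active_hamiltonian(ints, scf, act)
  e_det <- ha$e_core + 2 * ha$h_eff[1, 1] + ha$g_act[1, 1, 1, 1]
  expect_equal(e_det, scf$hf_energy, tolerance = 1e-9)
})

test_that("e_core + active FCI energy is invariant under active rotations", {
  ints <- water_ints(); scf <- water_scf()
  act <- select_active_space(scf, 4L, 3:6)
  e0 <- fci_solve(build_active_hamiltonian(ints, scf, act))$energy
  set.seed(11)
  K <- matrix(rnorm(16), 4); K <- K - t(K)
  U <- with(eigen(-1i * K), Re(vectors %*% (exp(1i * values) * Conj(t(vectors)))))
  C <- scf$mo_coefficients
  C[, act$active_indices] <- C[, act$active_indices] %*% U
  e1 <- fci_solve(build_active_hamiltonian(ints, C, act))$energy
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("qubit accounting follows the encoding", {
  expect_equal(n_qubits_for(4, "jw"), 8)
  expect_equal(n_qubits_for(4, "parity"), 6)
  expect_equal(n_qubits_for(2, "parity"), 2)
})
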