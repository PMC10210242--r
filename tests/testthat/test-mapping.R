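test_that("Jordan-Wigner maps number operators to (I - Z)/2", {
  f0 <- fermion_operator(2, list(qcasscf:::.fterm(c(0L, 0L), c(1L, 0L), 1)))
  q0 <- jordan_wigner(f0)
  expect_setequal(q0$labels, c("II", "ZI"))
  expect_equal(q0$coefs[match("II", q0$labels)], 0.5 + 0i)
  expect_equal(q0$coefs[match("ZI", q0$labels)], -0.5 + 0i)

  f1 <- fermion_operator(2, list(qcasscf:::.fterm(c(1L, 1L), c(1L, 0L), 1)))
  q1 <- jordan_wigner(f1)
  expect_setequal(q1$labels, c("II", "IZ"))
  expect_equal(q1$coefs[match("IZ", q1$labels)], -0.5 + 0i)
})

test_that("JW image equals the dense Fock-space matrix of the preimage", {
  # the oracle builds creation/annihilation matrices directly from the
  # occupation-number definition with explicit parity signs
  set.seed(4)
  terms <- list(
    qcasscf:::.fterm(c(0L, 2L), c(1L, 0L), 0.7),
    qcasscf:::.fterm(c(2L, 0L), c(1L, 0L), 0.7),
    qcasscf:::.fterm(c(0L, 1L, 3L, 2L), c(1L, 1L, 0L, 0L), -0.3),
    qcasscf:::.fterm(c(2L, 3L, 1L, 0L), c(1L, 1L, 0L, 0L), -0.3),
    qcasscf:::.fterm(c(3L, 3L), c(1L, 0L), 1.1)
  )
  f <- fermion_operator(4, terms)
  expect_equal(max(Mod(qop_matrix(jordan_wigner(f)) -
                         qcasscf:::.fermion_matrix(f))), 0, tolerance = 1e-12)
})

test_that("to_spin_orbitals doubles the orbital count and blocks spins", {
  ha <- random_active_h(2, 2, seed = 5)
  f <- to_spin_orbitals(ha)
  expect_equal(f$n_spin_orbitals, 4)
  # diagonal one-body only: -1.0 (a+_0 a_0 + a+_1 a_1) over both spins
  hd <- structure(list(h_eff = matrix(-1), g_act = array(0, rep(1, 4)),
                       e_core = 0, n_active_electrons = 1L,
                       n_active_orbitals = 1L, sz2 = 1L),
                  class = "qc_active_hamiltonian")
  fd <- to_spin_orbitals(hd)
  M <- qcasscf:::.fermion_matrix(fd)
  expect_equal(Re(diag(M)), c(0, -1, -1, -2)) # |00>, |10>, |01>, |11>
})

test_that("mapped Hamiltonian matrix equals the direct Fock-space build", {
  ha <- random_active_h(2, 2, seed = 6)
  Mq <- qop_matrix(qubit_hamiltonian(ha, "jw"))
  Mf <- qcasscf:::.fermion_matrix(to_spin_orbitals(ha))
  expect_equal(max(Mod(Mq - Mf)), 0, tolerance = 1e-11)
})

test_that("parity mapping with two-qubit reduction preserves sector spectra", {
  for (seed in 1:3) {
    ha <- random_active_h(2, 2, seed = seed)
    sec <- list(n_electrons = 2L, sz2 = 0L)
    sp_jw <- sector_spectrum(qubit_hamiltonian(ha, "jw"), sec, 2, "jw")
    qp <- qubit_hamiltonian(ha, "parity")
    expect_equal(qp$n_qubits, 2)
    sp_par <- sector_spectrum(qp, sec, 2, "parity")
    expect_equal(sp_jw, sp_par, tolerance = 1e-10)
  }
  # open-shell sector on 3 orbitals
  ha3 <- random_active_h(3, 3, seed = 9, sz2 = 1L)
  sec3 <- list(n_electrons = 3L, sz2 = 1L)
  sp_jw <- sector_spectrum(qubit_hamiltonian(ha3, "jw"), sec3, 3, "jw")
  sp_par <- sector_spectrum(qubit_hamiltonian(ha3, "parity", sz2 = 1L),
                            sec3, 3, "parity")
  expect_equal(sp_jw, sp_par, tolerance = 1e-10)
})

test_that("the total-number operator is constant in the reduced space", {
  n_orb <- 2L
  terms <- lapply(0:3, function(j) qcasscf:::.fterm(c(j, j), c(1L, 0L), 1))
  f <- fermion_operator(4, terms)
  q <- parity_map_reduced(f, n_elec = 2L, sz2 = 0L)
  expect_equal(q$labels, "II")
  expect_equal(Re(q$coefs), 2)
})

test_that("sector-symmetry violations in the parity reduction are caught", {
  f <- fermion_operator(4, list(qcasscf:::.fterm(3L, 1L, 1))) # bare a+_3
  expect_error(parity_map_reduced(f, 2L, 0L), "sector symmetry")
})

test_that("simplify merges, prunes, and never grows the term count", {
  q <- qubit_operator(1, c("X", "X"), c(1, -1))
  expect_length(simplify_qop(q)$labels, 0)
  q2 <- qubit_operator(1, "Z", 1e-14)
  expect_length(simplify_qop(q2, tol = 1e-12)$labels, 0)
  set.seed(8)
  labs <- replicate(20, paste0(sample(c("I", "X", "Y", "Z"), 3, TRUE),
                               collapse = ""))
  q3 <- qubit_operator(3, labs, rnorm(20))
  q3s <- simplify_qop(q3, tol = 0)
  expect_lte(length(q3s$labels), length(q3$labels))
  expect_equal(qop_matrix(q3s), qop_matrix(q3), tolerance = 1e-12)
})

test_that("Hermitian fermion operators map to real-coefficient Pauli sums", {
  ha <- random_active_h(2, 2, seed = 10)
  expect_true(qop_is_hermitian(qubit_hamiltonian(ha, "jw")))
  expect_true(qop_is_hermitian(qubit_hamiltonian(ha, "parity")))
})

test_that("excitation-operator images behave on reference determinants", {
  ops <- rdm_component_operators(2, "jw")
  ref <- prepare_reference(2, 1, 1, "jw") # |1100> blocked: qubits 0 and 2
  expect_equal(expectation(ref, ops$E[[1]][[1]]), 2)
  expect_equal(expectation(ref, ops$E[[2]][[2]]), 0)
  total_n <- qop_add(ops$E[[1]][[1]], ops$E[[2]][[2]])
  expect_equal(expectation(ref, total_n), 2)
  expect_equal(expectation(ref, ops$e[[1]][[1]][[1]][[1]]), 2)
})

test_that("qubit-operator text serialization round-trips", {
  ha <- random_active_h(2, 2, seed = 12)
  q <- qubit_hamiltonian(ha, "jw")
  q2 <- qop_deserialize(qop_serialize(q), q$n_qubits)
  expect_equal(qop_matrix(q2), qop_matrix(q), tolerance = 1e-12)
})
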