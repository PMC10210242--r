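test_that("exact expectations match dense-matrix quadratic forms", {
  expect_equal(expectation(basis_state(1), qubit_operator(1, "Z", 1)), 1)
  set.seed(13)
  amps <- complex(real = rnorm(8), imaginary = rnorm(8))
  amps <- amps / sqrt(sum(Mod(amps)^2))
  st <- statevector(amps)
  expect_equal(expectation(st, qop_identity(3)), 1, tolerance = 1e-12)
  labs <- c("XYZ", "ZIX", "YYI", "III")
  q <- qubit_operator(3, labs, rnorm(4))
  M <- qop_matrix(q)
  expect_equal(expectation(st, q),
               Re(Conj(amps) %*% M %*% amps)[1], tolerance = 1e-12)
  expect_error(expectation(st, qubit_operator(3, "XII", 1i), check = TRUE),
               "Hermitian")
})

test_that("gates act as expected on statevectors", {
  # Ry(pi) |0> = |1>; CX creates the Bell correlation; H^2 = I
  s <- gate_ry(basis_state(1), 0, pi)
  expect_equal(Mod(s$amps[2]), 1, tolerance = 1e-12)
  b <- gate_cx(gate_h(basis_state(2), 0), 0, 1)
  expect_equal(Mod(b$amps[c(1, 4)]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(expectation(b, qubit_operator(2, "ZZ", 1)), 1, tolerance = 1e-12)
  s2 <- gate_h(gate_h(basis_state(1), 0), 0)
  expect_equal(s2$amps, basis_state(1)$amps, tolerance = 1e-12)
})

test_that("the HF reference state reproduces the SCF energy", {
  ints <- water_ints(); scf <- water_scf()
  # HOMO-skipping window: inactive (incl. the HOMO) plus the two lowest
  # active orbitals reproduce the aufbau HF determinant
  act <- select_active_space(scf, 4L, c(3L, 4L, 6L, 7L))
  ha <- build_active_hamiltonian(ints, scf, act)
  for (enc in c("jw", "parity")) {
    ref <- prepare_reference(4, 2, 2, enc)
    qh <- qubit_hamiltonian(ha, enc)
    expect_equal(expectation(ref, qh), scf$hf_energy, tolerance = 1e-9)
  }
})

test_that("open-shell references have the alpha excess", {
  ref <- prepare_reference(3, 2, 1, "jw")
  ops <- rdm_component_operators(3, "jw")
  occ <- vapply(1:3, function(p) expectation(ref, ops$E[[p]][[p]]), numeric(1))
  expect_equal(occ, c(2, 1, 0))
})

test_that("UCCSD at zero amplitudes is the reference; states stay normalized", {
  spec <- uccsd_spec(2, 1, 1, "jw")
  expect_equal(spec$n_params, 3) # 2 same-spin singles + 1 alpha-beta double
  st0 <- apply_uccsd(NULL, rep(0, 3), spec)
  expect_equal(st0$amps, spec$reference$amps, tolerance = 1e-14)
  set.seed(14)
  ha <- random_active_h(2, 2, seed = 14)
  qh <- qubit_hamiltonian(ha, "jw")
  e_fci <- fci_solve(ha)$energy
  for (k in 1:5) {
    st <- apply_uccsd(NULL, runif(3, -1, 1), spec)
    expect_equal(sv_norm(st), 1, tolerance = 1e-10)
    expect_gte(expectation(st, qh), e_fci - 1e-10)
  }
})

test_that("UCCSD-VQE is exact for CAS(2,2) and variational elsewhere", {
  for (seed in c(21, 22)) {
    ha <- random_active_h(2, 2, seed = seed)
    res <- vqe_minimize(qubit_hamiltonian(ha, "jw"), uccsd_spec(2, 1, 1, "jw"))
    expect_equal(res$energy, fci_solve(ha)$energy, tolerance = 1e-9)
    expect_true(all(diff(range(res$optimizer_trace$energy)) >= 0))
  }
  # CAS(4,4)-style fixture: bounded below by FCI
  ha4 <- random_active_h(4, 4, seed = 23, scale = 0.1)
  res4 <- vqe_minimize(qubit_hamiltonian(ha4, "jw"), uccsd_spec(4, 2, 2, "jw"),
                       optimizer = optimizer_spec("BFGS", maxit = 60))
  expect_gte(res4$energy, fci_solve(ha4)$energy - 1e-9)
})

test_that("a constant Hamiltonian needs no optimization", {
  spec <- uccsd_spec(2, 1, 1, "jw")
  res <- vqe_minimize(qop_identity(4, 2.5), spec)
  expect_equal(res$energy, 2.5, tolerance = 1e-12)
})

test_that("HEA with zero parameters is the all-zero state", {
  spec <- hea_spec(2, 1)
  expect_equal(spec$n_params, 8)
  st <- apply_hea(rep(0, 8), spec)
  expect_equal(Mod(st$amps[1]), 1, tolerance = 1e-12)
})

test_that("HEA-VQE reaches the FCI energy of a 2-qubit reduced CAS(2,2)", {
  ha <- random_active_h(2, 2, seed = 31)
  qh <- qubit_hamiltonian(ha, "parity")
  res <- vqe_minimize(qh, hea_spec(2, 1), seed = 2)
  expect_equal(res$energy, fci_solve(ha)$energy, tolerance = 1e-7)
})

test_that("sampled expectations are deterministic outcomes or unbiased", {
  st <- basis_state(1)
  z <- qubit_operator(1, "Z", 1)
  expect_equal(sampled_expectation(st, z, shots = 50, seed = 1), 1)
  x <- qubit_operator(1, "X", 1)
  vals <- vapply(1:60, function(s) sampled_expectation(st, x, 1000, seed = s),
                 numeric(1))
  expect_lt(abs(mean(vals)), 3 / sqrt(1000 * 60))
  expect_lt(abs(sd(vals) - 1 / sqrt(1000)), 0.01)
})

test_that("full depolarizing noise kills traceless expectations", {
  st <- basis_state(1)
  z <- qubit_operator(1, "Z", 1)
  noise <- noise_spec(depolarizing_1q = 1, shots = 2000)
  vals <- vapply(1:20, function(s)
    sampled_expectation(st, z, 2000, noise = noise, seed = s), numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("shot-noise standard error scales like shots^(-1/2)", {
  st <- gate_ry(basis_state(1), 0, pi / 3) # <Z> = cos(pi/3) = 0.5
  z <- qubit_operator(1, "Z", 1)
  sds <- vapply(c(100, 400, 1600), function(shots) {
    sd(vapply(1:80, function(s) sampled_expectation(st, z, shots, seed = s),
              numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_gt(sds[1] / sds[2], 1.5); expect_lt(sds[1] / sds[2], 2.7)
  expect_gt(sds[2] / sds[3], 1.5); expect_lt(sds[2] / sds[3], 2.7)
})

test_that("measured RDMs conserve the particle number", {
  ha <- random_active_h(3, 4, seed = 33)
  gs <- fci_solve(ha)
  rd <- measure_rdms(gs$state, rdm_component_operators(3, "jw"))
  expect_equal(sum(diag(rd$dm1)), 4, tolerance = 1e-9)
  expect_equal(active_energy(ha, rd), gs$energy, tolerance = 1e-9)
})
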