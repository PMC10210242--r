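test_that("density-matrix circuit simulation matches the statevector", {
  spec <- hea_spec(2, 1)
  set.seed(71)
  params <- runif(spec$n_params, -pi, pi)
  st <- apply_hea(params, spec)
  rho <- simulate_density_matrix(hea_gates(params, spec), 2, noise = NULL)
  ha <- random_active_h(2, 2, seed = 71)
  qh <- qubit_hamiltonian(ha, "parity")
  e_sv <- expectation(st, qh)
  e_dm <- Re(sum(diag(qop_matrix(qh) %*% rho)))
  expect_equal(e_dm, e_sv, tolerance = 1e-10)
  expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-12)
})

test_that("noisy energy error grows monotonically with depolarizing rate", {
  spec <- hea_spec(2, 1)
  ha <- random_active_h(2, 2, seed = 72)
  qh <- qubit_hamiltonian(ha, "parity")
  res <- vqe_minimize(qh, spec, seed = 5)
  e0 <- res$energy
  gates <- hea_gates(res$parameters, spec)
  err <- vapply(c(0, 0.05, 0.25), function(p) {
    noise <- noise_spec(depolarizing_1q = p, shots = 4000)
    vals <- vapply(1:10, function(s) {
      set.seed(s)
      noisy_estimator(gates, 2, noise)(qh)
    }, numeric(1))
    abs(mean(vals) - e0)
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("readout confusion biases sampled expectations as predicted", {
  # <Z> on |0> through a symmetric flip channel f shrinks to 1 - 2f
  noise <- noise_spec(readout_flip = 0.1, shots = 200000)
  z <- qubit_operator(1, "Z", 1)
  v <- sampled_expectation(basis_state(1), z, noise$shots, noise = noise,
                           seed = 3)
  expect_equal(v, 1 - 2 * 0.1, tolerance = 0.02)
})

test_that("benchmark runs are deterministic given the seed", {
  ints <- water_ints(); scf <- water_scf()
  actspec <- list(n_elec = 2, indices = c(scf$n_alpha - 1L, scf$n_alpha + 1L))
  cfg <- bench_config(ints, actspec, scf = scf, max_macro = 3L,
                      spsa = optimizer_spec("SPSA", maxit = 10L))
  r1 <- qcasscf:::.bench_single(cfg, seed = 11)
  r2 <- qcasscf:::.bench_single(cfg, seed = 11)
  expect_identical(r1$trace$energy, r2$trace$energy)
  r3 <- qcasscf:::.bench_single(cfg, seed = 12)
  expect_false(identical(r1$trace$energy, r3$trace$energy))
})

test_that("dispersion statistics require at least two repeats", {
  ints <- water_ints(); scf <- water_scf()
  cfg <- bench_config(ints, list(n_elec = 2, n_orb = 2), scf = scf)
  expect_error(run_repeated(cfg, n_repeats = 1), "n_repeats")
})

test_that("compare_canonical rejects configs differing beyond the flag", {
  ints <- water_ints(); scf <- water_scf()
  a <- bench_config(ints, list(n_elec = 2, n_orb = 2), scf = scf,
                    canonical = TRUE)
  b <- bench_config(ints, list(n_elec = 2, n_orb = 2), scf = scf,
                    canonical = FALSE, max_macro = 5L)
  expect_error(compare_canonical(a, b, 2), "max_macro")
  expect_error(compare_canonical(a, a, 2), "same canonical flag")
})

test_that("the noiseless benchmark limit reproduces the FCI-driver energy", {
  ints <- water_ints(); scf <- water_scf()
  actspec <- list(n_elec = 2, indices = c(scf$n_alpha - 1L, scf$n_alpha + 1L))
  e_fci <- run_casscf(ints, actspec, driver = "FCI", scf = scf)$energy
  for (canonical in c(TRUE, FALSE)) {
    cfg <- bench_config(ints, actspec, noise = NULL, canonical = canonical,
                        scf = scf, energy_tol = 1e-7,
                        spsa = optimizer_spec("BFGS"))
    res <- qcasscf:::.bench_single(cfg, seed = 2)
    expect_equal(res$energy, e_fci, tolerance = 1e-5)
  }
})
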