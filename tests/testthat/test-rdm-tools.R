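test_that("normalization rescales the 1-RDM trace to N and is idempotent", {
  r <- rdm_pair(diag(c(1.9, 0)), array(0, rep(2, 4)), 2)
  r1 <- normalize_dm1(r)
  expect_equal(r1$dm1, diag(c(2, 0)))
  expect_equal(normalize_dm1(r1)$dm1, r1$dm1, tolerance = 1e-14)
  expect_error(normalize_dm1(rdm_pair(diag(c(0, 0)), array(0, rep(2, 4)), 2)),
               "degenerate")
})

test_that("symmetrization is the nearest symmetric matrix and keeps the trace", {
  r <- rdm_pair(matrix(c(2, 0.3, 0.1, 0), 2, 2, byrow = TRUE),
                array(0, rep(2, 4)), 2)
  rs <- symmetrize_dm1(r)
  expect_equal(rs$dm1, matrix(c(2, 0.2, 0.2, 0), 2, 2))
  expect_equal(sum(diag(rs$dm1)), sum(diag(r$dm1)))
  # projection property: no symmetric matrix is closer in Frobenius norm
  set.seed(41)
  d0 <- sqrt(sum((r$dm1 - rs$dm1)^2))
  for (k in 1:20) {
    s <- matrix(rnorm(4), 2); s <- (s + t(s)) / 2
    expect_gte(sqrt(sum((r$dm1 - s)^2)), d0 - 1e-12)
  }
  expect_equal(symmetrize_dm1(rs)$dm1, rs$dm1)
})

test_that("canonicalization diagonalizes with descending occupations", {
  r <- rdm_pair(diag(c(1.8, 0.2)), array(0, rep(2, 4)), 2,
                flags = c(normalized = TRUE, symmetrized = TRUE,
                          canonicalized = FALSE))
  out <- canonicalize(r)
  expect_equal(out$transform$rotation, diag(2))
  expect_equal(out$transform$occupations, c(1.8, 0.2))

  ha <- random_active_h(3, 4, seed = 42)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(3, "jw"))
  out2 <- canonicalize(symmetrize_dm1(normalize_dm1(rd)))
  U <- out2$transform$rotation
  expect_equal(crossprod(U), diag(3), tolerance = 1e-10)
  expect_equal(sum(out2$transform$occupations), 4, tolerance = 1e-9)
  expect_true(all(diff(out2$transform$occupations) <= 1e-12))
  expect_true(max(abs(out2$rdms$dm1 - diag(diag(out2$rdms$dm1)))) < 1e-10)
})

test_that("exact RDMs are a fixed point of the constraint pipeline", {
  ha <- random_active_h(3, 2, seed = 43)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(3, "jw"))
  proc <- constrain_dm2(symmetrize_dm1(normalize_dm1(rd)))
  expect_equal(proc$dm2, rd$dm2, tolerance = 1e-10)
  expect_equal(proc$dm1, rd$dm1, tolerance = 1e-10)
})

test_that("constraint projection restores the contraction identities exactly", {
  ha <- random_active_h(3, 4, seed = 44)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(3, "jw"))
  set.seed(44)
  rd$dm1 <- rd$dm1 + matrix(rnorm(9, sd = 0.02), 3)
  rd$dm2 <- rd$dm2 + array(rnorm(81, sd = 0.02), rep(3, 4))
  proc <- constrain_dm2(symmetrize_dm1(normalize_dm1(rd)))
  n <- 3; N <- 4
  ptr <- matrix(0, n, n)
  for (k in 1:n) ptr <- ptr + proc$dm2[, , k, k]
  expect_equal(ptr, (N - 1) * proc$dm1, tolerance = 1e-10)
  expect_equal(sum(diag(ptr)), N * (N - 1), tolerance = 1e-10)
  # index symmetries of a real-wavefunction 2-RDM
  expect_equal(proc$dm2, aperm(proc$dm2, c(2, 1, 4, 3)), tolerance = 1e-12)
  expect_equal(proc$dm2, aperm(proc$dm2, c(3, 4, 1, 2)), tolerance = 1e-12)
})

test_that("the full post-processing pipeline is idempotent", {
  ha <- random_active_h(3, 4, seed = 45)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(3, "jw"))
  set.seed(45)
  rd$dm1 <- rd$dm1 + matrix(rnorm(9, sd = 0.05), 3)
  rd$dm2 <- rd$dm2 + array(rnorm(81, sd = 0.05), rep(3, 4))
  once <- process_rdms(rd, canonical = TRUE)
  twice <- process_rdms(once$rdms, canonical = TRUE)
  expect_equal(twice$rdms$dm1, once$rdms$dm1, tolerance = 1e-12)
  expect_equal(twice$rdms$dm2, once$rdms$dm2, tolerance = 1e-12)
  expect_equal(twice$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sum(diag(once$rdms$dm1)), 4, tolerance = 1e-12)
})

test_that("noisy occupations are clipped into [0, 2] and renormalized", {
  dm1 <- diag(c(2.3, 1.9, -0.2))
  r <- clip_occupations(rdm_pair(dm1, array(0, rep(3, 4)), 4))
  occ <- natural_occupations(r)
  expect_true(all(occ >= -1e-12 & occ <= 2 + 1e-12))
  expect_equal(sum(occ), 4, tolerance = 1e-9)
})

test_that("canonicalization keeps the energy when integrals are co-rotated", {
  ha <- random_active_h(3, 4, seed = 46)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(3, "jw"))
  e0 <- active_energy(ha, rd)
  out <- process_rdms(rd, canonical = TRUE)
  U <- out$transform$rotation
  ha2 <- ha
  ha2$h_eff <- t(U) %*% ha$h_eff %*% U
  ha2$g_act <- qcasscf:::.transform_eri(ha$g_act, U)
  expect_equal(active_energy(ha2, out$rdms), e0, tolerance = 1e-9)
})

test_that("noncanonical mode skips only the canonicalization step", {
  ha <- random_active_h(3, 4, seed = 47)
  rd <- measure_rdms(fci_solve(ha)$state, rdm_component_operators(3, "jw"))
  out <- process_rdms(rd, canonical = FALSE)
  expect_equal(out$transform$rotation, diag(3))
  expect_false(unname(out$rdms$flags["canonicalized"]))
  expect_true(unname(out$rdms$flags["normalized"]))
  expect_true(unname(out$rdms$flags["symmetrized"]))
})
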