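# Shared fixtures, built in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

water_geometry <- function() {
  read_xyz(system.file("extdata", "geometries", "water_synthetic.xyz",
                       package = "qcasscf"))
}

co_geometry <- function() {
  read_xyz(system.file("extdata", "geometries", "co_1.54.xyz",
                       package = "qcasscf"))
}

h2_geometry <- function(r = 0.74) {
  parse_xyz(sprintf("2\nH2\nH 0 0 0\nH 0 0 %.6f", r))
}

water_ints <- function() cached("water_ints", {
  compute_ao_integrals(water_geometry(), "sto-3g")
})

water_scf <- function() cached("water_scf", run_hf(water_ints()))

co_ints <- function() cached("co_ints", {
  compute_ao_integrals(co_geometry(), "cc-pvdz")
})

co_scf <- function() cached("co_scf", run_hf(co_ints()))

# random active-space Hamiltonian with the physical integral symmetries
random_active_h <- function(n_orb, n_elec, seed, scale = 0.3, sz2 = NULL) {
  set.seed(seed)
  h <- matrix(rnorm(n_orb^2), n_orb)
  h <- (h + t(h)) / 2
  g <- array(rnorm(n_orb^4), rep(n_orb, 4)) * scale
  gs <- array(0, rep(n_orb, 4))
  for (perm in list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3),
                    c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 1, 2),
                    c(3, 4, 2, 1), c(4, 3, 2, 1))) {
    gs <- gs + aperm(g, perm)
  }
  if (is.null(sz2)) sz2 <- n_elec %% 2L
  structure(list(h_eff = h, g_act = gs / 8, e_core = rnorm(1),
                 n_active_electrons = as.integer(n_elec),
                 n_active_orbitals = as.integer(n_orb),
                 sz2 = as.integer(sz2)),
            class = "qc_active_hamiltonian")
}

# exact FCI solve of an active Hamiltonian (JW route)
fci_solve <- function(h_act) {
  sector <- list(n_electrons = h_act$n_active_electrons, sz2 = h_act$sz2)
  ground_state(qubit_hamiltonian(h_act, "jw"), sector,
               h_act$n_active_orbitals, "jw")
}
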