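# Synthetic active-space fixtures: reproducible FCIDUMP files plus a sidecar
# with exact reference values computed by the exact solver.

#' Generate a synthetic active-space fixture
#'
#' Kinds: "random_hamiltonian" (dense random symmetric integrals),
#' "hubbard_like" (nearest-neighbour hopping + on-site repulsion), and
#' "stretched_diatomic" (a 2-orbital two-site model with tunable gap/coupling,
#' qualitatively mimicking a dissociating sigma bond). Each fixture is exactly
#' solvable by [ground_state()]; the sidecar records ground energy and natural
#' occupations.
#'
#' @param kind fixture family.
#' @param n_orb active orbitals (<= 6).
#' @param n_elec active electrons (default n_orb).
#' @param seed RNG seed; identical seeds give identical files.
#' @param path output FCIDUMP path (sidecar gets extension .json).
#' @return invisibly, a list with `h_act`, `energy`, `occupations`, `path`,
#'   `sidecar`.
#' @export
generate_fixture <- function(kind = c("random_hamiltonian", "hubbard_like",
                                      "stretched_diatomic"),
                             n_orb = 2L, n_elec = NULL, seed = 1L,
                             path = tempfile(fileext = ".fcidump")) {
  kind <- match.arg(kind)
  if (n_orb > 6L) stop("fixtures are capped at 6 orbitals")
  if (is.null(n_elec)) n_elec <- n_orb
  set.seed(seed)
  n <- n_orb
  if (kind == "random_hamiltonian") {
    h <- matrix(stats::rnorm(n * n), n)
    h <- (h + t(h)) / 2
    g <- array(stats::rnorm(n^4), rep(n, 4)) * 0.2
    gs <- array(0, rep(n, 4))
    for (perm in list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3),
                      c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 1, 2),
                      c(3, 4, 2, 1), c(4, 3, 2, 1))) {
      gs <- gs + aperm(g, perm)
    }
    g <- gs / 8
    e_core <- stats::rnorm(1)
  } else if (kind == "hubbard_like") {
    t_hop <- 1
    u <- 2 + stats::runif(1)
    h <- matrix(0, n, n)
    for (i in seq_len(n - 1)) { h[i, i + 1] <- -t_hop; h[i + 1, i] <- -t_hop }
    g <- array(0, rep(n, 4))
    for (i in seq_len(n)) g[i, i, i, i] <- u
    e_core <- 0
  } else {
    if (n != 2L) stop("stretched_diatomic fixture is a 2-orbital model")
    # H2-like sigma bond in the bonding/antibonding MO basis; shrinking the
    # orbital gap mimics stretching (growing double-excitation weight) while
    # the ground state stays a closed-shell-dominated singlet
    gap <- stats::runif(1, 0.3, 1.2)
    k_ex <- stats::runif(1, 0.15, 0.25)
    h <- diag(c(-1.2, -1.2 + gap))
    g <- array(0, rep(n, 4))
    g[1, 1, 1, 1] <- 0.67; g[2, 2, 2, 2] <- 0.70
    g[1, 1, 2, 2] <- 0.66; g[2, 2, 1, 1] <- 0.66
    g[1, 2, 1, 2] <- k_ex; g[2, 1, 2, 1] <- k_ex
    g[1, 2, 2, 1] <- k_ex; g[2, 1, 1, 2] <- k_ex
    e_core <- stats::runif(1, 0.3, 1)     # nuclear-repulsion-like offset
  }
  sz2 <- n_elec %% 2L
  h_act <- structure(list(h_eff = h, g_act = g, e_core = e_core,
                          n_active_electrons = as.integer(n_elec),
                          n_active_orbitals = n, sz2 = sz2),
                     class = "qc_active_hamiltonian")
  gs <- ground_state(qubit_hamiltonian(h_act, "jw"),
                     list(n_electrons = n_elec, sz2 = sz2), n, "jw")
  rd <- exact_rdms(gs$state, n, "jw")
  occ <- natural_occupations(rd)
  write_fcidump(h_act, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(kind = kind, seed = seed, n_orb = n, n_elec = n_elec,
         ground_energy = gs$energy, occupations = occ),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(h_act = h_act, energy = gs$energy, occupations = occ,
                 path = path, sidecar = sidecar))
}
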