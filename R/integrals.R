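# AO integrals (spherical basis) and four-index tensor transformations.

# One-sided transform of a 4-index tensor: g[p,q,r,s] -> sum_p g * M[p, i]
# applied to each index in turn. M is (dim_in x dim_out).
.transform_eri <- function(g, M) {
  n_in <- nrow(M); n_out <- ncol(M)
  d <- dim(g)
  for (k in 1:4) {
    # bring index k to the front, multiply, put it at the back
    g <- aperm(g, c(k, setdiff(1:4, k)))
    dim(g) <- c(d[k], length(g) / d[k])
    g <- crossprod(M, g) # n_out x rest
    dnew <- c(n_out, d[setdiff(1:4, k)])
    dim(g) <- dnew
    g <- aperm(g, order(c(k, setdiff(1:4, k))))
    d <- dim(g)
  }
  g
}

#' Compute AO integrals
#'
#' Overlap, core Hamiltonian (kinetic + nuclear attraction), two-electron
#' repulsion integrals in chemists' notation (pq|rs), and the nuclear
#' repulsion energy, all in the real-spherical contracted AO basis.
#'
#' @param geom a `qc_geometry`.
#' @param basis basis-set name or basis file path (see [build_basis()]).
#' @return object of class `qc_ao_integrals` with elements `overlap`,
#'   `core_hamiltonian`, `eri` (4-index array, 8-fold symmetric),
#'   `nuclear_repulsion`, `n_basis`.
#' @export
compute_ao_integrals <- function(geom, basis) {
  bas <- if (inherits(basis, "qc_basis")) basis else build_basis(geom, basis)
  one <- cpp_one_electron(bas$shells, as.numeric(geom$z), geom$xyz_bohr)
  C <- bas$c2s
  S <- crossprod(C, one$S %*% C)
  H <- crossprod(C, (one$T + one$V) %*% C)
  g <- cpp_eri(bas$shells)
  g <- .transform_eri(g, C)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    warning("overlap matrix nearly singular (min eigenvalue ",
            format(min(ev)), ")")
  }
  structure(list(
    overlap = S, core_hamiltonian = H, eri = g,
    nuclear_repulsion = nuclear_repulsion(geom),
    n_basis = bas$n_basis, basis = bas, geometry = geom
  ), class = "qc_ao_integrals")
}

#' Transform AO integrals to an MO basis
#'
#' @param ints a `qc_ao_integrals`.
#' @param C MO coefficient matrix (n_basis x n_mo), orthonormal under the
#'   overlap metric.
#' @return list with `h` (one-electron MO matrix) and `g` (MO ERIs, (pq|rs)).
#' @export
mo_integrals <- function(ints, C) {
  list(h = crossprod(C, ints$core_hamiltonian %*% C),
       g = .transform_eri(ints$eri, C))
}
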