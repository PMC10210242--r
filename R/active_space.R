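# Active-space selection and effective Hamiltonian construction.

#' Select an active space
#'
#' Chooses the inactive space as the lowest-energy doubly occupied MOs not in
#' `active_indices`, so that inactive electrons + `n_elec` equals the total
#' electron count; everything else is virtual. Indices need not be contiguous.
#'
#' @param scf a `qc_scf` result.
#' @param n_elec number of active electrons.
#' @param active_indices 1-based MO indices of the active orbitals, in
#'   ascending energy order.
#' @return object of class `qc_active_space`.
#' @export
select_active_space <- function(scf, n_elec, active_indices) {
  n_mo <- scf$n_mo
  active_indices <- as.integer(active_indices)
  if (any(active_indices < 1L | active_indices > n_mo)) {
    stop("active index out of range")
  }
  if (anyDuplicated(active_indices)) stop("duplicate active indices")
  n_act <- length(active_indices)
  if (n_elec < 0 || n_elec > 2L * n_act) {
    stop("active electron count must lie in [0, 2 * n_orbitals]")
  }
  total <- scf$n_alpha + scf$n_beta
  n_inact_elec <- total - n_elec
  if (n_inact_elec %% 2L != 0L) {
    stop("inactive space must be closed shell: total - active electrons ",
         "is odd (", n_inact_elec, ")")
  }
  n_inact <- n_inact_elec %/% 2L
  candidates <- setdiff(order(scf$mo_energies), active_indices)
  if (n_inact > length(candidates)) stop("not enough orbitals for the inactive space")
  inactive <- sort(candidates[seq_len(n_inact)])
  virtual <- sort(setdiff(seq_len(n_mo), c(active_indices, inactive)))
  n_open <- scf$n_alpha - scf$n_beta
  structure(list(
    n_active_electrons = as.integer(n_elec),
    active_indices = active_indices,
    inactive_indices = inactive,
    virtual_indices = virtual,
    sz2 = as.integer(n_open)
  ), class = "qc_active_space")
}

#' Effective active-space Hamiltonian
#'
#' One-body part h_eff(u,v) = h(u,v) + sum_i [2 (uv|ii) - (ui|iv)] over
#' inactive i (the inactive Fock matrix restricted to the active block),
#' two-body part the active block of the MO ERIs, and core energy
#' e_core = E_nuc + sum_i [h(i,i) + F_inactive(i,i)].
#'
#' @param ints a `qc_ao_integrals`.
#' @param scf a `qc_scf` (supplies the MO coefficients) or a plain MO
#'   coefficient matrix.
#' @param act a `qc_active_space`.
#' @param mo optional precomputed [mo_integrals()] result for the same
#'   coefficients (saves the AO->MO transform).
#' @return object of class `qc_active_hamiltonian`: `h_eff`, `g_act`,
#'   `e_core`, `n_active_electrons`, `n_active_orbitals`.
#' @export
build_active_hamiltonian <- function(ints, scf, act, mo = NULL) {
  C <- if (is.matrix(scf)) scf else scf$mo_coefficients
  if (is.null(mo)) mo <- mo_integrals(ints, C)
  h <- mo$h; g <- mo$g
  ia <- act$inactive_indices
  aa <- act$active_indices
  n_act <- length(aa)
  # inactive Fock in full MO basis
  Fi <- h
  if (length(ia)) {
    Fi <- Fi + 2 * apply(g[, , ia, ia, drop = FALSE], c(1, 2),
                         function(m) sum(diag(as.matrix(m)))) -
      apply(g[, ia, ia, , drop = FALSE], c(1, 4),
            function(m) sum(diag(as.matrix(m))))
  }
  e_core <- ints$nuclear_repulsion +
    (if (length(ia)) sum(diag(h)[ia] + diag(Fi)[ia]) else 0)
  h_eff <- Fi[aa, aa, drop = FALSE]
  g_act <- g[aa, aa, aa, aa, drop = FALSE]
  structure(list(
    h_eff = (h_eff + t(h_eff)) / 2,
    g_act = g_act,
    e_core = e_core,
    n_active_electrons = act$n_active_electrons,
    n_active_orbitals = n_act,
    sz2 = act$sz2
  ), class = "qc_active_hamiltonian")
}

#' Energy of an active-space Hamiltonian with given RDMs
#'
#' E = e_core + sum_pq h_eff dm1 + 1/2 sum_pqrs (pq|rs) dm2.
#'
#' @param h_act a `qc_active_hamiltonian`.
#' @param rdms a `qc_rdm_pair`.
#' @return total energy (Hartree).
#' @export
active_energy <- function(h_act, rdms) {
  h_act$e_core + sum(h_act$h_eff * rdms$dm1) +
    0.5 * sum(h_act$g_act * rdms$dm2)
}
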