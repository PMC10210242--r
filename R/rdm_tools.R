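# RDM post-processing: normalization, symmetrization, canonicalization
# (natural orbitals), and 2-RDM constraint enforcement. Conventions
# (Mulliken / chemists' pair ordering, matching the (pq|rs) ERIs):
# spin-summed dm1 with trace N; dm2[p,q,r,s] = <E_pq E_rs - delta_qr E_ps>
# with partial trace sum_r dm2[p,q,r,r] = (N-1) dm1[p,q] and full trace
# sum_{p,r} dm2[p,p,r,r] = N (N-1).

#' Normalize the 1-RDM to trace N
#' @param r a `qc_rdm_pair`.
#' @return a `qc_rdm_pair` with dm1 scaled by N / tr(dm1).
#' @export
normalize_dm1 <- function(r) {
  tr <- sum(diag(r$dm1))
  if (tr <= 0) stop("degenerate measurement: 1-RDM trace is ", tr)
  r$dm1 <- r$dm1 * (r$n_electrons / tr)
  r$flags["normalized"] <- TRUE
  r
}

#' Symmetrize the 1-RDM
#' @param r a `qc_rdm_pair`.
#' @return a `qc_rdm_pair` with dm1 replaced by (dm1 + dm1^T)/2. This is the
#'   Frobenius-nearest symmetric matrix; the trace is preserved.
#' @export
symmetrize_dm1 <- function(r) {
  r$dm1 <- (r$dm1 + t(r$dm1)) / 2
  r$flags["symmetrized"] <- TRUE
  r
}

# rotate a 4-index tensor by U on every index: d'[t,u,v,w] =
# sum d[p,q,r,s] U[p,t] U[q,u] U[r,v] U[s,w]
.rotate_dm2 <- function(d2, U) {
  .transform_eri(d2, U)
}

#' Canonicalize the RDMs (natural orbitals)
#'
#' Diagonalizes the (symmetric) 1-RDM; returns RDMs expressed in the natural
#' orbital basis (dm1 diagonal with descending occupations, dm2 co-rotated on
#' all four indices) plus the orthogonal rotation to apply to the active MO
#' coefficient columns. The rotation is made deterministic by ordering
#' eigenvalues descending and fixing the sign of each eigenvector's
#' largest-magnitude component to be positive.
#'
#' @param r a `qc_rdm_pair` with symmetric dm1.
#' @return list: `rdms` (canonicalized `qc_rdm_pair`), `transform`
#'   (list `occupations`, `rotation`).
#' @export
canonicalize <- function(r) {
  if (max(abs(r$dm1 - t(r$dm1))) > 1e-8) {
    stop("dm1 must be symmetrized before canonicalization")
  }
  ev <- eigen((r$dm1 + t(r$dm1)) / 2, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)
  occ <- ev$values[ord]
  U <- ev$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(U))) {
    imax <- which.max(abs(U[, k]))
    if (U[imax, k] < 0) U[, k] <- -U[, k]
  }
  r$dm1 <- diag(occ, nrow = length(occ))
  r$dm2 <- .rotate_dm2(r$dm2, U)
  r$flags["canonicalized"] <- TRUE
  list(rdms = r, transform = list(occupations = occ, rotation = U))
}

#' Clip natural occupations into [0, 2] and renormalize
#'
#' Noise can push 1-RDM eigenvalues outside the physical range; this projects
#' the spectrum onto [0, 2] and rescales to trace N.
#'
#' @param r a `qc_rdm_pair` with symmetric dm1.
#' @return a `qc_rdm_pair`.
#' @export
clip_occupations <- function(r) {
  ev <- eigen((r$dm1 + t(r$dm1)) / 2, symmetric = TRUE)
  N <- r$n_electrons
  # Euclidean projection of the spectrum onto {0 <= v <= 2, sum v = N}:
  # v_i = clamp(e_i + tau, 0, 2) with tau chosen so the trace is N
  vfun <- function(tau) pmin(pmax(ev$values + tau, 0), 2)
  if (abs(sum(vfun(0)) - N) < 1e-14) {
    vals <- vfun(0)
  } else {
    lo <- -max(ev$values); hi <- 2 - min(ev$values)
    tau <- stats::uniroot(function(t) sum(vfun(t)) - N, c(lo, hi),
                          tol = 1e-14)$root
    vals <- vfun(tau)
  }
  r$dm1 <- ev$vectors %*% (vals * t(ev$vectors))
  r
}

#' Impose 2-RDM constraints
#'
#' Three steps: (1) symmetrize dm2 over its index group for a real
#' wavefunction -- hermiticity (p,q,r,s) -> (q,p,s,r) and pair exchange
#' (p,q,r,s) -> (r,s,p,q) -- (2) rescale so sum_{p,r} dm2[p,p,r,r] = N (N-1),
#' (3) restore the partial-trace identity sum_r dm2[p,q,r,r] = (N-1) dm1[p,q]
#' exactly by adding the symmetric projection tensor
#' (delta_rs D_pq + delta_pq D_rs) / n, where D is the (traceless, symmetric)
#' partial-trace defect. Exact noiseless RDMs are a fixed point, and the full
#' pipeline is idempotent.
#'
#' @param r a `qc_rdm_pair` whose dm1 is already normalized and symmetrized.
#' @return a `qc_rdm_pair`.
#' @export
constrain_dm2 <- function(r) {
  n <- nrow(r$dm1)
  N <- r$n_electrons
  d <- r$dm2
  d <- (d +
          aperm(d, c(2, 1, 4, 3)) +
          aperm(d, c(3, 4, 1, 2)) +
          aperm(d, c(4, 3, 2, 1))) / 4
  # partial trace over the second pair: ptr[p,q] = sum_r d[p,q,r,r]
  ptr <- function(x) {
    out <- matrix(0, n, n)
    for (k in seq_len(n)) out <- out + x[, , k, k]
    out
  }
  full_tr <- sum(diag(ptr(d)))
  if (N > 1 && abs(full_tr) > 1e-12) {
    d <- d * (N * (N - 1) / full_tr)
  }
  Dft <- (N - 1) * r$dm1 - ptr(d)  # partial-trace defect, symmetric, traceless
  Dft <- (Dft + t(Dft)) / 2
  Dft <- Dft - diag(sum(diag(Dft)) / n, n)
  if (max(abs(Dft)) > 0) {
    del <- diag(n)
    corr <- array(0, c(n, n, n, n))
    for (p in 1:n) for (q in 1:n) for (rr in 1:n) for (ss in 1:n) {
      corr[p, q, rr, ss] <- (del[rr, ss] * Dft[p, q] +
                               del[p, q] * Dft[rr, ss]) / n
    }
    d <- d + corr
  }
  r$dm2 <- d
  r
}

#' Full RDM post-processing pipeline
#'
#' Normalization, symmetrization, 2-RDM constraints, and (by default)
#' canonicalization to natural orbitals. With `canonical = FALSE` the
#' canonicalization step is skipped and the identity rotation returned.
#' Under noise, occupations are clipped into [0, 2] first.
#'
#' @param r a raw `qc_rdm_pair`.
#' @param canonical canonicalize to natural orbitals?
#' @param clip clip unphysical occupations (recommended for noisy input).
#' @return list `rdms`, `transform` as in [canonicalize()].
#' @export
process_rdms <- function(r, canonical = TRUE, clip = FALSE) {
  r <- normalize_dm1(r)
  r <- symmetrize_dm1(r)
  if (clip) r <- clip_occupations(r)
  r <- constrain_dm2(r)
  if (canonical) {
    canonicalize(r)
  } else {
    n <- nrow(r$dm1)
    list(rdms = r, transform = list(occupations = sort(diag(r$dm1),
                                                       decreasing = TRUE),
                                    rotation = diag(n)))
  }
}

#' Natural occupations of an RDM pair
#' @param r a `qc_rdm_pair`.
#' @return descending eigenvalues of the symmetrized dm1.
#' @export
natural_occupations <- function(r) {
  sort(eigen((r$dm1 + t(r$dm1)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}
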