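# FCIDUMP (Molpro dialect) import/export of active-space Hamiltonians:
# 1-based indices, 8-fold permutational symmetry of the two-body integrals,
# core energy on the all-zero index line, &FCI NORB/NELEC/MS2 header.

#' Write an active-space Hamiltonian to an FCIDUMP file
#'
#' @param h_act a `qc_active_hamiltonian`.
#' @param path output file path.
#' @param tol integrals with |value| <= tol are not written.
#' @return invisibly, the path.
#' @export
write_fcidump <- function(h_act, path, tol = 0) {
  n <- h_act$n_active_orbitals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, h_act$n_active_electrons,
            if (is.null(h_act$sz2)) 0L else h_act$sz2),
    sprintf(" ORBSYM=%s", paste(rep("1", n), collapse = ",")),
    " ISYM=1,",
    "&END"
  ), con)
  fmt <- function(v, p, q, r, s) sprintf("%23.16e %4d %4d %4d %4d", v, p, q, r, s)
  lines <- character(0)
  for (p in 1:n) for (q in 1:p) for (r in 1:p) {
    smax <- if (r == p) q else r
    for (s in 1:smax) {
      v <- h_act$g_act[p, q, r, s]
      if (abs(v) > tol) lines <- c(lines, fmt(v, p, q, r, s))
    }
  }
  for (p in 1:n) for (q in 1:p) {
    v <- h_act$h_eff[p, q]
    if (abs(v) > tol) lines <- c(lines, fmt(v, p, q, 0L, 0L))
  }
  lines <- c(lines, fmt(h_act$e_core, 0L, 0L, 0L, 0L))
  writeLines(lines, con)
  invisible(path)
}

#' Read an FCIDUMP file into an active-space Hamiltonian
#'
#' @param path FCIDUMP file path.
#' @return a `qc_active_hamiltonian`.
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  head_end <- grep("&END|/\\s*$", lines)[1]
  if (is.na(head_end)) stop("FCIDUMP header terminator not found")
  header <- paste(lines[1:head_end], collapse = " ")
  getnum <- function(key) {
    m <- regmatches(header, regexec(paste0(key, "\\s*=\\s*(-?[0-9]+)"), header))[[1]]
    if (length(m) < 2) stop("FCIDUMP header missing ", key)
    as.integer(m[2])
  }
  n <- getnum("NORB")
  nelec <- getnum("NELEC")
  ms2 <- tryCatch(getnum("MS2"), error = function(e) 0L)
  h <- matrix(0, n, n)
  g <- array(0, c(n, n, n, n))
  e_core <- 0
  for (ln in lines[(head_end + 1L):length(lines)]) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    v <- as.numeric(f[1])
    p <- as.integer(f[2]); q <- as.integer(f[3])
    r <- as.integer(f[4]); s <- as.integer(f[5])
    if (p == 0) {
      e_core <- v
    } else if (r == 0) {
      h[p, q] <- v; h[q, p] <- v
    } else {
      for (ix in list(c(p, q, r, s), c(q, p, r, s), c(p, q, s, r),
                      c(q, p, s, r), c(r, s, p, q), c(s, r, p, q),
                      c(r, s, q, p), c(s, r, q, p))) {
        g[ix[1], ix[2], ix[3], ix[4]] <- v
      }
    }
  }
  structure(list(h_eff = h, g_act = g, e_core = e_core,
                 n_active_electrons = nelec, n_active_orbitals = n,
                 sz2 = ms2), class = "qc_active_hamiltonian")
}
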