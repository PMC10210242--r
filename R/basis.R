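# Basis-set handling: plain-text shell data -> normalized contracted shells,
# Cartesian-to-spherical transformation matrices.

.l_codes <- c(S = 0L, P = 1L, D = 2L)

#' Read a basis-definition file
#'
#' The bundled format lists, per element, shells of type S/P/D/SP with one
#' exponent + coefficient(s) line per primitive (SP carries the s and p
#' coefficient columns). Exponents are in inverse Bohr^2, as usual.
#'
#' @param path path to a basis file; the names "sto-3g", "6-31g" and "cc-pvdz"
#'   resolve to the bundled sets.
#' @return a named list: element symbol -> list of shells
#'   (each `list(l =, exps =, coefs =)`).
#' @export
read_basis <- function(path) {
  if (!file.exists(path)) {
    builtin <- system.file("extdata", "basis",
                           paste0(tolower(path), ".bas"), package = "qcasscf")
    if (!nzchar(builtin)) {
      stop("unknown basis set or missing basis file: ", path)
    }
    path <- builtin
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  out <- list()
  cur <- NULL
  i <- 1L
  while (i <= length(lines)) {
    fields <- strsplit(lines[i], "\\s+")[[1]]
    if (fields[1] == "element") {
      cur <- fields[2]
      out[[cur]] <- list()
      i <- i + 1L
    } else {
      type <- toupper(fields[1])
      nprim <- as.integer(fields[2])
      rows <- do.call(rbind, lapply(lines[(i + 1L):(i + nprim)], function(ln) {
        as.numeric(strsplit(ln, "\\s+")[[1]])
      }))
      if (type == "SP") {
        out[[cur]] <- c(out[[cur]],
                        list(list(l = 0L, exps = rows[, 1], coefs = rows[, 2]),
                             list(l = 1L, exps = rows[, 1], coefs = rows[, 3])))
      } else {
        l <- .l_codes[[type]]
        out[[cur]] <- c(out[[cur]],
                        list(list(l = l, exps = rows[, 1], coefs = rows[, 2])))
      }
      i <- i + 1L + nprim
    }
  }
  out
}

# Normalize contraction coefficients so raw Cartesian primitives
# x^lx y^ly z^lz exp(-a r^2) can be used directly: scale each coefficient by
# the primitive norm of the (l,0,0) component, then rescale the contraction to
# unit self-overlap of that component.
.normalize_shell <- function(shell) {
  l <- shell$l
  a <- shell$exps
  dfact <- c(1, 1, 3, 15)[l + 1] # (2l-1)!!
  nprim <- (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(dfact)
  c1 <- shell$coefs * nprim
  pp <- outer(a, a, "+")
  s_ll <- sum(outer(c1, c1) * (pi / pp)^1.5 * dfact / (2 * pp)^l)
  shell$coefs <- c1 / sqrt(s_ll)
  shell
}

# Cartesian -> real-spherical transformation for one shell.
# Cartesian order for d: xx, xy, xz, yy, yz, zz (engine convention).
.c2s_block <- function(l) {
  if (l == 0L) return(matrix(1, 1, 1))
  if (l == 1L) return(diag(3))
  if (l == 2L) {
    m <- matrix(0, 6, 5)
    s3 <- sqrt(3)
    m[2, 1] <- s3                      # d_{-2} ~ sqrt(3) xy
    m[5, 2] <- s3                      # d_{-1} ~ sqrt(3) yz
    m[1, 3] <- -0.5; m[4, 3] <- -0.5; m[6, 3] <- 1   # d_0 ~ (2zz-xx-yy)/2
    m[3, 4] <- s3                      # d_{+1} ~ sqrt(3) xz
    m[1, 5] <- s3 / 2; m[4, 5] <- -s3 / 2            # d_{+2} ~ sqrt(3)(xx-yy)/2
    return(m)
  }
  stop("angular momentum l > 2 not supported")
}

#' Build the shell list for a molecule
#'
#' @param geom a `qc_geometry`.
#' @param basis basis-set name ("sto-3g", "6-31g", "cc-pvdz") or path to a
#'   basis file in the bundled format.
#' @return object of class `qc_basis` with normalized shells (centers in Bohr),
#'   the Cartesian->spherical matrix, and the spherical basis dimension.
#' @export
build_basis <- function(geom, basis) {
  defs <- read_basis(basis)
  shells <- list()
  for (iat in seq_along(geom$atoms)) {
    el <- geom$atoms[iat]
    if (is.null(defs[[el]])) {
      stop("basis '", basis, "' has no data for element ", el)
    }
    for (sh in defs[[el]]) {
      sh <- .normalize_shell(sh)
      sh$center <- geom$xyz_bohr[iat, ]
      shells[[length(shells) + 1L]] <- sh
    }
  }
  ls <- vapply(shells, function(s) s$l, integer(1))
  ncart <- as.integer(sum((ls + 1) * (ls + 2) / 2))
  nsph <- as.integer(sum(2L * ls + 1L))
  c2s <- matrix(0, ncart, nsph)
  ro <- 0L; co <- 0L
  for (s in shells) {
    blk <- .c2s_block(s$l)
    c2s[ro + seq_len(nrow(blk)), co + seq_len(ncol(blk))] <- blk
    ro <- ro + nrow(blk); co <- co + ncol(blk)
  }
  structure(list(shells = shells, c2s = c2s, n_basis = nsph, n_cart = ncart,
                 name = basis), class = "qc_basis")
}

#' Number of contracted (spherical) basis functions
#' @param geom a `qc_geometry`.
#' @param basis basis name or file.
#' @return integer count of contracted functions (= number of MOs).
#' @export
count_basis_functions <- function(geom, basis) {
  build_basis(geom, basis)$n_basis
}
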