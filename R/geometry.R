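#' @useDynLib qcasscf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bohr radius in Angstrom; all internal lengths are Bohr, energies Hartree.
ANGSTROM_PER_BOHR <- 0.52917721092

.element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

#' Atomic number of an element symbol
#' @param symbol character vector of element symbols (e.g. "C", "O").
#' @return integer vector of nuclear charges.
#' @export
atomic_number <- function(symbol) {
  z <- .element_numbers[symbol]
  if (any(is.na(z))) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(z)], collapse = ", "))
  }
  unname(z)
}

#' Construct a molecular geometry
#'
#' Coordinates are given in Angstrom and stored both in Angstrom and Bohr.
#'
#' @param atoms character vector of element symbols.
#' @param xyz numeric matrix (n_atoms x 3) of Cartesian coordinates in Angstrom.
#' @param charge total molecular charge.
#' @param multiplicity spin multiplicity 2S+1.
#' @return object of class `qc_geometry`.
#' @export
geometry <- function(atoms, xyz, charge = 0L, multiplicity = 1L) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(atoms) != nrow(xyz)) stop("atoms and xyz sizes differ")
  z <- atomic_number(atoms)
  n_elec <- sum(z) - charge
  if ((n_elec - (multiplicity - 1L)) %% 2L != 0L) {
    stop("multiplicity ", multiplicity,
         " inconsistent with electron count ", n_elec)
  }
  structure(list(
    atoms = atoms, xyz = xyz, xyz_bohr = xyz / ANGSTROM_PER_BOHR,
    charge = as.integer(charge), multiplicity = as.integer(multiplicity),
    z = z, n_electrons = n_elec
  ), class = "qc_geometry")
}

#' Parse an XYZ-format string
#'
#' Standard XYZ convention: atom count line, comment line, then one
#' `symbol x y z` line per atom (coordinates in Angstrom).
#'
#' @param text XYZ file contents as a single string (or vector of lines).
#' @param charge,multiplicity passed to [geometry()].
#' @return a `qc_geometry`.
#' @export
parse_xyz <- function(text, charge = 0L, multiplicity = 1L) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 1L || !nzchar(trimws(lines[1]))) {
    stop("XYZ format error: missing atom count line")
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ format error: unparsable atom count on line 1")
  if (length(lines) < n + 2L) {
    stop("XYZ format error: expected ", n, " atom lines, found ",
         max(0L, length(lines) - 2L))
  }
  atoms <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 2L]), "\\s+")[[1]]
    if (length(fields) < 4L) {
      stop("XYZ format error on line ", i + 2L, ": need 'symbol x y z'")
    }
    atoms[i] <- fields[1]
    coord <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(coord))) {
      stop("XYZ format error on line ", i + 2L, ": unparsable coordinate")
    }
    xyz[i, ] <- coord
  }
  geometry(atoms, xyz, charge = charge, multiplicity = multiplicity)
}

#' Read a geometry from an XYZ file
#' @param path file path.
#' @inheritParams parse_xyz
#' @return a `qc_geometry`.
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  parse_xyz(readLines(path), charge = charge, multiplicity = multiplicity)
}

#' Write a geometry to an XYZ file
#' @param geom a `qc_geometry`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(geom, path, comment = "") {
  lines <- c(
    as.character(length(geom$atoms)), comment,
    sprintf("%-2s %18.12f %18.12f %18.12f", geom$atoms,
            geom$xyz[, 1], geom$xyz[, 2], geom$xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.qc_geometry <- function(x, ...) {
  cat(sprintf("Geometry: %d atoms, charge %d, multiplicity %d, %d electrons\n",
              length(x$atoms), x$charge, x$multiplicity, x$n_electrons))
  for (i in seq_along(x$atoms)) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$atoms[i],
                x$xyz[i, 1], x$xyz[i, 2], x$xyz[i, 3]))
  }
  invisible(x)
}

#' Nuclear repulsion energy (Hartree)
#' @param geom a `qc_geometry`.
#' @return energy in Hartree.
#' @export
nuclear_repulsion <- function(geom) {
  n <- length(geom$atoms)
  e <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((geom$xyz_bohr[i, ] - geom$xyz_bohr[j, ])^2))
      e <- e + geom$z[i] * geom$z[j] / r
    }
  }
  e
}
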