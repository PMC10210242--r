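# Pauli-string algebra: QubitOperator = weighted sum of Pauli strings.
# A label is a character string over {I,X,Y,Z}; position j (1-based) acts on
# qubit j-1. Coefficients are stored as complex; Hermitian operators have
# (numerically) real coefficients after simplification.

.pauli_code <- c(I = 0L, X = 1L, Y = 2L, Z = 3L)
.pauli_char <- c("I", "X", "Y", "Z")

# product tables: code of P_a P_b, and the power of i in its phase
.prod_tab <- matrix(c(
  0L, 1L, 2L, 3L,
  1L, 0L, 3L, 2L,
  2L, 3L, 0L, 1L,
  3L, 2L, 1L, 0L), 4, 4, byrow = TRUE)
.iexp_tab <- matrix(c(
  0L, 0L, 0L, 0L,
  0L, 0L, 1L, 3L,
  0L, 3L, 0L, 1L,
  0L, 1L, 3L, 0L), 4, 4, byrow = TRUE)

.labels_to_codes <- function(labels) {
  if (length(labels) == 0L) return(matrix(integer(0), 0, 0))
  n <- nchar(labels[1])
  m <- matrix(.pauli_code[unlist(strsplit(labels, ""), use.names = FALSE)],
              ncol = n, byrow = TRUE)
  m
}

.codes_to_labels <- function(codes) {
  if (nrow(codes) == 0L) return(character(0))
  apply(codes, 1, function(r) paste0(.pauli_char[r + 1L], collapse = ""))
}

#' Construct a qubit operator
#'
#' @param n_qubits number of qubits.
#' @param labels character vector of Pauli-string labels over I/X/Y/Z
#'   (length `n_qubits` each); position j acts on qubit j-1.
#' @param coefs numeric or complex coefficients, one per label.
#' @return object of class `qc_qubit_op`.
#' @export
qubit_operator <- function(n_qubits, labels = character(0), coefs = complex(0)) {
  stopifnot(length(labels) == length(coefs))
  if (length(labels) && any(nchar(labels) != n_qubits)) {
    stop("all labels must have length n_qubits")
  }
  structure(list(n_qubits = as.integer(n_qubits),
                 labels = labels, coefs = as.complex(coefs)),
            class = "qc_qubit_op")
}

#' Identity operator times a scalar
#' @param n_qubits number of qubits.
#' @param c scalar coefficient.
#' @return a `qc_qubit_op`.
#' @export
qop_identity <- function(n_qubits, c = 1) {
  qubit_operator(n_qubits, strrep("I", n_qubits), as.complex(c))
}

#' Merge like terms and drop negligible coefficients
#'
#' @param q a `qc_qubit_op`.
#' @param tol coefficients with modulus <= `tol` are removed.
#' @return simplified `qc_qubit_op`; term count never increases.
#' @export
simplify_qop <- function(q, tol = 1e-12) {
  if (length(q$labels) == 0L) return(q)
  re <- rowsum(cbind(Re(q$coefs), Im(q$coefs)), group = q$labels)
  coefs <- complex(real = re[, 1], imaginary = re[, 2])
  labels <- rownames(re)
  keep <- Mod(coefs) > tol
  qubit_operator(q$n_qubits, labels[keep], coefs[keep])
}

#' Sum of qubit operators
#' @param ... `qc_qubit_op` objects on the same qubit count.
#' @param simplify merge like terms afterwards.
#' @return a `qc_qubit_op`.
#' @export
qop_add <- function(..., simplify = TRUE) {
  ops <- list(...)
  n <- ops[[1]]$n_qubits
  q <- qubit_operator(n, unlist(lapply(ops, `[[`, "labels")),
                      unlist(lapply(ops, `[[`, "coefs")))
  if (simplify) simplify_qop(q) else q
}

#' Scale a qubit operator
#' @param q a `qc_qubit_op`.
#' @param c scalar.
#' @return a `qc_qubit_op`.
#' @export
qop_scale <- function(q, c) {
  qubit_operator(q$n_qubits, q$labels, q$coefs * as.complex(c))
}

#' Product of two qubit operators
#' @param q1,q2 `qc_qubit_op` objects on the same qubit count.
#' @param simplify merge like terms afterwards.
#' @return a `qc_qubit_op` representing q1 %*% q2.
#' @export
qop_mul <- function(q1, q2, simplify = TRUE) {
  n <- q1$n_qubits
  if (q2$n_qubits != n) stop("qubit counts differ")
  t1 <- length(q1$labels); t2 <- length(q2$labels)
  if (t1 == 0L || t2 == 0L) return(qubit_operator(n))
  c1 <- .labels_to_codes(q1$labels)
  c2 <- .labels_to_codes(q2$labels)
  A <- c1[rep(seq_len(t1), each = t2), , drop = FALSE]
  B <- c2[rep(seq_len(t2), times = t1), , drop = FALSE]
  res <- matrix(.prod_tab[cbind(as.vector(A) + 1L, as.vector(B) + 1L)],
                nrow = t1 * t2)
  iexp <- matrix(.iexp_tab[cbind(as.vector(A) + 1L, as.vector(B) + 1L)],
                 nrow = t1 * t2)
  phase <- (0+1i)^(rowSums(iexp) %% 4L)
  coefs <- rep(q1$coefs, each = t2) * rep(q2$coefs, times = t1) * phase
  q <- qubit_operator(n, .codes_to_labels(res), coefs)
  if (simplify) simplify_qop(q) else q
}

#' Hermitian conjugate of a qubit operator
#' @param q a `qc_qubit_op`.
#' @return a `qc_qubit_op`.
#' @export
qop_dagger <- function(q) {
  qubit_operator(q$n_qubits, q$labels, Conj(q$coefs))
}

#' Is the operator Hermitian (real coefficients after simplification)?
#' @param q a `qc_qubit_op`.
#' @param tol imaginary-part tolerance.
#' @return logical.
#' @export
qop_is_hermitian <- function(q, tol = 1e-10) {
  qs <- simplify_qop(q, tol = 0)
  length(qs$coefs) == 0L || max(abs(Im(qs$coefs))) < tol
}

# bit masks (x / y / z) for each term; qubit j = bit j of the basis index
.qop_masks <- function(q) {
  codes <- .labels_to_codes(q$labels)
  if (nrow(codes) == 0L) {
    return(list(x = integer(0), y = integer(0), z = integer(0)))
  }
  pow <- 2L^(seq_len(ncol(codes)) - 1L)
  list(
    x = as.integer(drop((codes == 1L) %*% pow)),
    y = as.integer(drop((codes == 2L) %*% pow)),
    z = as.integer(drop((codes == 3L) %*% pow))
  )
}

#' Dense matrix representation of a qubit operator
#'
#' Basis ordering: index b (0-based) has qubit j occupied iff bit j of b is 1;
#' matrix row/column r corresponds to b = r - 1.
#'
#' @param q a `qc_qubit_op`.
#' @return complex matrix of dimension 2^n x 2^n.
#' @export
qop_matrix <- function(q) {
  n <- q$n_qubits
  N <- 2L^n
  M <- matrix(0+0i, N, N)
  masks <- .qop_masks(q)
  src <- 0:(N - 1L)
  for (k in seq_along(q$labels)) {
    flip <- bitwOr(masks$x[k], masks$y[k])
    tgt <- bitwXor(src, flip)
    par <- .popcount(bitwAnd(src, bitwOr(masks$y[k], masks$z[k])))
    ny <- .popcount(masks$y[k])
    phase <- (0+1i)^(ny %% 4L) * (-1)^(par %% 2L)
    M[cbind(tgt + 1L, src + 1L)] <- M[cbind(tgt + 1L, src + 1L)] +
      q$coefs[k] * phase
  }
  M
}

.popcount <- function(v) {
  out <- integer(length(v))
  while (any(v > 0L)) {
    out <- out + bitwAnd(v, 1L)
    v <- bitwShiftR(v, 1L)
  }
  out
}

#' Serialize a qubit operator to text lines
#'
#' One line per term: "re<TAB>im<TAB>label", sorted by label for stable
#' golden-file comparisons.
#' @param q a `qc_qubit_op`.
#' @return character vector of lines.
#' @export
qop_serialize <- function(q) {
  qs <- simplify_qop(q)
  ord <- order(qs$labels)
  sprintf("%.15g\t%.15g\t%s", Re(qs$coefs)[ord], Im(qs$coefs)[ord],
          qs$labels[ord])
}

#' Parse the serialization produced by [qop_serialize()]
#' @param lines character vector of lines.
#' @param n_qubits qubit count.
#' @return a `qc_qubit_op`.
#' @export
qop_deserialize <- function(lines, n_qubits) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  qubit_operator(
    n_qubits,
    vapply(parts, `[`, "", 3L),
    complex(real = as.numeric(vapply(parts, `[`, "", 1L)),
            imaginary = as.numeric(vapply(parts, `[`, "", 2L)))
  )
}

#' @export
print.qc_qubit_op <- function(x, ...) {
  cat(sprintf("QubitOperator on %d qubits, %d terms\n",
              x$n_qubits, length(x$labels)))
  m <- min(10L, length(x$labels))
  for (k in seq_len(m)) {
    cat(sprintf("  %s  %s\n", x$labels[k], format(x$coefs[k], digits = 8)))
  }
  if (length(x$labels) > m) cat("  ...\n")
  invisible(x)
}
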