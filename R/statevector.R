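# Statevector utilities and sparse fermionic operators in the qubit basis.
#
# Occupation convention: spin orbital q (0-based, interleaved ordering) maps
# to qubit q; qubit 0 is the leftmost tensor factor (bit weight 2^(n-1)).
# Fermionic signs follow the Jordan-Wigner parity of the occupied spin
# orbitals below q.

.state_n_qubits <- function(state) {
  n <- as.integer(round(log2(length(state))))
  if (2^n != length(state)) stop("state length is not a power of two")
  n
}

#' Hartree-Fock reference state
#'
#' Computational basis state with the `n_active_electrons` lowest-indexed spin
#' orbitals occupied (interleaved ordering), i.e. `|11...100...0>`.
#'
#' @param active an `active_space`, or an integer number of qubits (then
#'   `n_electrons` must be given).
#' @param n_electrons electron count when `active` is an integer.
#' @return complex statevector of length `2^n_qubits`.
#' @export
hf_reference_state <- function(active, n_electrons = NULL) {
  if (inherits(active, "active_space")) {
    n <- active$n_qubits
    ne <- active$n_active_electrons
  } else {
    n <- as.integer(active)
    ne <- n_electrons
  }
  if (ne > n) stop("more electrons than spin orbitals")
  w <- .qubit_weights(n)
  idx <- if (ne > 0) sum(w[seq_len(ne)]) else 0
  v <- complex(2^n)
  v[idx + 1] <- 1 + 0i
  v
}

# sparse matrix (real) of a single ladder operator a_q or a+_q
.ladder_sparse <- function(q, dagger, n) {
  dim <- 2^n
  w <- .qubit_weights(n)
  wq <- w[q + 1]
  below <- if (q > 0) sum(w[seq_len(q)]) else 0
  pc <- .popcount_table(n)
  b <- 0:(dim - 1)
  occ <- bitwAnd(b, wq) > 0
  src <- if (dagger) b[!occ] else b[occ]
  dst <- bitwXor(src, wq)
  sign <- (-1)^(pc[bitwAnd(src, below) + 1])
  Matrix::sparseMatrix(i = dst + 1, j = src + 1, x = sign, dims = c(dim, dim))
}

# sparse real matrix times complex vector
.smv <- function(M, v) {
  as.vector(M %*% Re(v)) + 1i * as.vector(M %*% Im(v))
}

#' Sparse matrix of a product of ladder operators
#'
#' @param qubits 0-based spin-orbital indices (applied right to left on kets,
#'   i.e. listed left to right as written in the operator product).
#' @param daggers logical vector.
#' @param n_qubits register size.
#' @return real sparse matrix (`Matrix::dgCMatrix`).
#' @export
ladder_operator_matrix <- function(qubits, daggers, n_qubits) {
  M <- NULL
  for (k in seq_along(qubits)) {
    L <- .ladder_sparse(qubits[k], daggers[k], n_qubits)
    M <- if (is.null(M)) L else M %*% L
  }
  M
}

# Spin-summed excitation operator E_pq = sum_sigma a+_{p sigma} a_{q sigma}
# over spatial orbitals (1-based), as a sparse real matrix.
.spatial_excitation_matrix <- function(p, q, n_qubits) {
  ladder_operator_matrix(c(spin_orbital_qubit(p, 0), spin_orbital_qubit(q, 0)),
                         c(TRUE, FALSE), n_qubits) +
  ladder_operator_matrix(c(spin_orbital_qubit(p, 1), spin_orbital_qubit(q, 1)),
                         c(TRUE, FALSE), n_qubits)
}

# Givens-type generators: G is real antisymmetric with G^3 = -G, so
# exp(theta G) v = v + sin(theta) G v + (1 - cos(theta)) G^2 v.
.single_excitation_generator <- function(q_from, q_to, n) {
  A <- ladder_operator_matrix(c(q_to, q_from), c(TRUE, FALSE), n)
  A - Matrix::t(A)
}

.paired_double_generator <- function(p_from, p_to, n) {
  # pair (p_from alpha, p_from beta) -> (p_to alpha, p_to beta), spatial 1-based
  A <- ladder_operator_matrix(
    c(spin_orbital_qubit(p_to, 0), spin_orbital_qubit(p_to, 1),
      spin_orbital_qubit(p_from, 1), spin_orbital_qubit(p_from, 0)),
    c(TRUE, TRUE, FALSE, FALSE), n)
  A - Matrix::t(A)
}

.apply_givens <- function(v, G, G2, theta) {
  if (theta == 0) return(v)
  v + sin(theta) * .smv(G, v) + (1 - cos(theta)) * .smv(G2, v)
}

# derivative of the gate applied to a vector: dU/dtheta v
.apply_givens_deriv <- function(v, G, G2, theta) {
  cos(theta) * .smv(G, v) + sin(theta) * .smv(G2, v)
}

#' Total particle-number operator as a sparse matrix
#' @param n_qubits register size.
#' @export
number_operator_matrix <- function(n_qubits) {
  dim <- 2^n_qubits
  pc <- .popcount_table(n_qubits)
  Matrix::sparseMatrix(i = 1:dim, j = 1:dim, x = pc, dims = c(dim, dim))
}
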