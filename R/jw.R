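# Jordan-Wigner mapping of the active-space Hamiltonian and of the ladder
# operators needed to measure the 1-RDM.
#
# Spin-orbital ordering (package-wide constant): interleaved
# (alpha_1, beta_1, alpha_2, beta_2, ...): spatial orbital p (1-based) with
# spin sigma (0 = alpha, 1 = beta) sits on qubit 2*(p-1) + sigma.

#' Qubit index of a spin orbital
#' @param p spatial orbital (1-based).
#' @param sigma spin: 0 = alpha, 1 = beta.
#' @export
spin_orbital_qubit <- function(p, sigma) 2L * (p - 1L) + as.integer(sigma)

# Product of ladder operators as Pauli terms, built directly on integer code
# matrices: each ladder operator contributes (X -+ iY)/2 on its qubit with a
# Z-string on all lower qubits (right multiplication, Eq. JW).
# `qubits` are 0-based, `daggers` logical, applied left to right.
.ladder_terms <- function(qubits, daggers, n) {
  codes <- matrix(1L, 1, n)
  coeffs <- complex(real = 1)
  for (k in seq_along(qubits)) {
    q <- qubits[k] + 1L
    m <- nrow(codes)
    cx <- codes; cy <- codes
    px <- coeffs; py <- coeffs
    if (q > 1) {
      for (col in seq_len(q - 1)) {
        idx <- cbind(codes[, col], rep(4L, m))
        ph <- .pmul_phase[idx]
        nc <- .pmul_code[idx]
        cx[, col] <- nc; cy[, col] <- nc
        px <- px * ph; py <- py * ph
      }
    }
    idxX <- cbind(codes[, q], rep(2L, m))
    idxY <- cbind(codes[, q], rep(3L, m))
    cx[, q] <- .pmul_code[idxX]
    cy[, q] <- .pmul_code[idxY]
    sgn <- if (daggers[k]) -1i else 1i
    px <- px * .pmul_phase[idxX] * 0.5
    py <- py * .pmul_phase[idxY] * (0.5 * sgn)
    codes <- rbind(cx, cy)
    coeffs <- c(px, py)
  }
  list(codes = codes, coeffs = coeffs)
}

.terms_to_pauli_op <- function(terms, n, tol = 1e-12) {
  keys <- apply(matrix(.pauli_chars[terms$codes], ncol = n), 1, paste,
                collapse = "")
  v <- tapply(terms$coeffs, keys, sum)
  v <- v[Mod(v) > tol]
  pauli_op(n, setNames(as.complex(v), names(v)))
}

#' Jordan-Wigner image of a product of ladder operators
#'
#' @param qubits 0-based qubit (spin-orbital) indices, applied left to right.
#' @param daggers logical vector: TRUE for creation operators.
#' @param n_qubits register size.
#' @return a `pauli_op`.
#' @export
jw_ladder_product <- function(qubits, daggers, n_qubits) {
  .terms_to_pauli_op(.ladder_terms(qubits, daggers, n_qubits), n_qubits)
}

#' Jordan-Wigner qubit Hamiltonian of an active-space Hamiltonian
#'
#' Maps `H = e_core + sum h_eff[pq] E_pq + 1/2 sum (pq|rs) sum_st
#' a+_ps a+_rt a_st a_qs` to a weighted sum of Pauli strings.  All
#' coefficients are real after assembly (asserted); terms below `tol` are
#' pruned and the identity string carries the constant part.
#'
#' @param ham an `active_hamiltonian`.
#' @param tol pruning threshold for Pauli coefficients.
#' @return a `pauli_op` on `2 * n_active_orbitals` qubits.
#' @export
jordan_wigner_hamiltonian <- function(ham, tol = 1e-12) {
  n_act <- ham$n_active_orbitals
  n <- 2L * n_act
  acc <- new.env(parent = emptyenv())
  add_terms <- function(terms, w) {
    keys <- apply(matrix(.pauli_chars[terms$codes], ncol = n), 1, paste,
                  collapse = "")
    vals <- terms$coeffs * w
    for (i in seq_along(keys)) {
      k <- keys[i]
      acc[[k]] <- if (is.null(acc[[k]])) vals[i] else acc[[k]] + vals[i]
    }
  }
  idmat <- matrix(1L, 1, n)
  add_terms(list(codes = idmat, coeffs = complex(real = 1)), ham$e_core)

  for (p in seq_len(n_act)) for (q in seq_len(n_act)) {
    hpq <- ham$h_eff[p, q]
    if (abs(hpq) < 1e-14) next
    for (s in 0:1) {
      add_terms(.ladder_terms(c(spin_orbital_qubit(p, s),
                                spin_orbital_qubit(q, s)),
                              c(TRUE, FALSE), n), hpq)
    }
  }
  for (p in seq_len(n_act)) for (q in seq_len(n_act)) {
    for (r in seq_len(n_act)) for (s in seq_len(n_act)) {
      gv <- ham$g[p, q, r, s]
      if (abs(gv) < 1e-14) next
      for (s1 in 0:1) for (s2 in 0:1) {
        add_terms(.ladder_terms(c(spin_orbital_qubit(p, s1),
                                  spin_orbital_qubit(r, s2),
                                  spin_orbital_qubit(s, s2),
                                  spin_orbital_qubit(q, s1)),
                                c(TRUE, TRUE, FALSE, FALSE), n), 0.5 * gv)
      }
    }
  }
  keys <- ls(acc)
  v <- vapply(keys, function(k) acc[[k]], complex(1))
  keep <- Mod(v) > tol
  v <- v[keep]; keys <- keys[keep]
  if (any(abs(Im(v)) > 1e-10)) {
    stop("JW mapping produced complex coefficients; Hermiticity violated")
  }
  pauli_op(n, setNames(complex(real = Re(v)), keys))
}

#' Hermitian measurement operators for a 1-RDM element
#'
#' For `p < q` returns the pair of Hermitian operators whose expectation
#' values are the real and imaginary parts of `D[pq] = <a+_p a_q>`:
#' `(a+_p a_q + a+_q a_p)/2` (the `(X X + Y Y)/4` form with a Z-string on
#' intervening qubits) and `(a+_p a_q - a+_q a_p)/(2i)`.  For `p = q` the
#' real part is the number operator `(I - Z_p)/2` and the imaginary part is
#' the zero operator.
#'
#' @param p,q 0-based spin-orbital (qubit) indices, `p <= q`.
#' @param n_qubits register size.
#' @return list with Hermitian `pauli_op`s `re` and `im`.
#' @export
jw_excitation_operator <- function(p, q, n_qubits) {
  if (p > q) stop("jw_excitation_operator requires p <= q")
  if (p == q) {
    w <- rep("I", n_qubits)
    id <- paste(w, collapse = "")
    w[p + 1] <- "Z"
    zs <- paste(w, collapse = "")
    re <- pauli_op(n_qubits, setNames(as.complex(c(0.5, -0.5)), c(id, zs)))
    return(list(re = re, im = pauli_op(n_qubits)))
  }
  apq <- .ladder_terms(c(p, q), c(TRUE, FALSE), n_qubits)
  aqp <- .ladder_terms(c(q, p), c(TRUE, FALSE), n_qubits)
  re <- .terms_to_pauli_op(list(codes = rbind(apq$codes, aqp$codes),
                                coeffs = 0.5 * c(apq$coeffs, aqp$coeffs)),
                           n_qubits)
  im <- .terms_to_pauli_op(list(codes = rbind(apq$codes, aqp$codes),
                                coeffs = c(apq$coeffs, -aqp$coeffs) / (2i)),
                           n_qubits)
  list(re = re, im = im)
}
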