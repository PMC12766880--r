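# Pauli-string operators on n qubits.
#
# Conventions (fixed package-wide): qubit 0 is the leftmost tensor factor, so
# basis index b = sum_q bit_q * 2^(n-1-q); a Pauli string is written as a word
# over {I, X, Y, Z} with position q acting on qubit q.

.pauli_codes <- c(I = 1L, X = 2L, Y = 3L, Z = 4L)
.pauli_chars <- c("I", "X", "Y", "Z")

# single-qubit products: code table and phase table (row = left, col = right)
.pmul_code <- matrix(c(1L,2L,3L,4L,
                       2L,1L,4L,3L,
                       3L,4L,1L,2L,
                       4L,3L,2L,1L), 4, 4, byrow = TRUE)
.pmul_phase <- matrix(c(1,1,1,1,
                        1,1,1i,-1i,
                        1,-1i,1,1i,
                        1,1i,-1i,1), 4, 4, byrow = TRUE)

#' Construct a Pauli-string operator
#'
#' @param n_qubits number of qubits.
#' @param terms named complex/numeric vector; names are words over `IXYZ` of
#'   length `n_qubits`, values the coefficients.
#' @return A `pauli_op`.
#' @export
pauli_op <- function(n_qubits, terms = setNames(complex(0), character(0))) {
  nm <- names(terms)
  terms <- as.complex(terms)   # as.complex drops names; restore them
  names(terms) <- nm
  if (length(terms) > 0 && any(nchar(names(terms)) != n_qubits)) {
    stop("Pauli word length must equal n_qubits")
  }
  structure(list(n_qubits = as.integer(n_qubits), terms = terms),
            class = "pauli_op")
}

#' @export
print.pauli_op <- function(x, ...) {
  cat(sprintf("<pauli_op on %d qubits, %d terms>\n", x$n_qubits,
              length(x$terms)))
  k <- head(order(-Mod(x$terms)), 8)
  for (i in k) {
    cat(sprintf("  %+.8f%+.8fi * %s\n", Re(x$terms[i]), Im(x$terms[i]),
                names(x$terms)[i]))
  }
  if (length(x$terms) > 8) cat("  ...\n")
  invisible(x)
}

.pauli_prune <- function(op, tol = 1e-12) {
  op$terms <- op$terms[Mod(op$terms) > tol]
  op
}

#' Sum and scalar multiple of Pauli operators
#' @param a,b `pauli_op`s on the same qubit count.
#' @export
pauli_add <- function(a, b) {
  stopifnot(a$n_qubits == b$n_qubits)
  keys <- union(names(a$terms), names(b$terms))
  v <- setNames(complex(length(keys)), keys)
  v[names(a$terms)] <- a$terms
  v[names(b$terms)] <- v[names(b$terms)] + b$terms
  .pauli_prune(pauli_op(a$n_qubits, v))
}

#' @rdname pauli_add
#' @param s scalar.
#' @export
pauli_scale <- function(a, s) pauli_op(a$n_qubits, a$terms * s)

#' Product of two Pauli operators
#' @param a,b `pauli_op`s on the same qubit count.
#' @export
pauli_multiply <- function(a, b) {
  stopifnot(a$n_qubits == b$n_qubits)
  acc <- new.env(parent = emptyenv())
  ca <- lapply(names(a$terms), function(s) .pauli_codes[strsplit(s, "")[[1]]])
  cb <- lapply(names(b$terms), function(s) .pauli_codes[strsplit(s, "")[[1]]])
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    idx <- cbind(ca[[i]], cb[[j]])
    code <- .pmul_code[idx]
    phase <- prod(.pmul_phase[idx])
    key <- paste(.pauli_chars[code], collapse = "")
    w <- a$terms[[i]] * b$terms[[j]] * phase
    acc[[key]] <- if (is.null(acc[[key]])) w else acc[[key]] + w
  }
  keys <- ls(acc)
  .pauli_prune(pauli_op(a$n_qubits,
                        setNames(vapply(keys, function(k) acc[[k]],
                                        complex(1)), keys)))
}

# --- fast compiled representation -----------------------------------------

# For string s: flip mask m (X/Y positions), phase(b) = i^{#Y} *
# (-1)^{popcount(b & zy_mask)} with zy_mask the Z/Y positions; then
# P |b> = phase(b) |b XOR m>.
.qubit_weights <- function(n) 2^(seq.int(n - 1, 0))   # weight of qubit q

.popcount_table <- function(n) {
  b <- 0:(2^n - 1)
  cnt <- integer(2^n)
  for (q in seq_len(n)) cnt <- cnt + bitwAnd(b, 2^(q - 1)) %/% 2^(q - 1)
  cnt
}

.compile_pauli <- function(op) {
  n <- op$n_qubits
  dim <- 2^n
  w <- .qubit_weights(n)
  pc <- .popcount_table(n)
  b <- 0:(dim - 1)
  lapply(seq_along(op$terms), function(i) {
    s <- strsplit(names(op$terms)[i], "")[[1]]
    xmask <- sum(w[s %in% c("X", "Y")])
    zymask <- sum(w[s %in% c("Z", "Y")])
    ny <- sum(s == "Y")
    phase <- (1i)^ny * (-1)^(pc[bitwAnd(b, zymask) + 1])
    list(coeff = op$terms[[i]], perm = bitwXor(b, xmask) + 1L, phase = phase)
  })
}

#' Expectation value of a Pauli operator on a statevector
#'
#' Exact (noiseless) evaluation of `sum_j alpha_j <psi|P_j|psi>`.  For a
#' Hermitian operator the result is real; the imaginary residue is checked
#' against `imag_tol` and dropped.
#'
#' @param state complex amplitude vector of length `2^n_qubits`.
#' @param op a `pauli_op` (or its compiled form).
#' @param imag_tol tolerance on the imaginary residue.
#' @export
pauli_expectation <- function(state, op, imag_tol = 1e-8) {
  compiled <- if (inherits(op, "pauli_op")) {
    if (length(state) != 2^op$n_qubits) stop("state/operator dimension mismatch")
    .compile_pauli(op)
  } else op
  val <- 0 + 0i
  for (t in compiled) {
    val <- val + t$coeff * sum(Conj(state[t$perm]) * t$phase * state)
  }
  if (abs(Im(val)) > imag_tol * max(1, abs(Re(val)))) {
    warning(sprintf("non-negligible imaginary expectation (%.3e)", Im(val)))
  }
  Re(val)
}

#' Apply a Pauli operator to a statevector
#' @inheritParams pauli_expectation
#' @export
pauli_apply <- function(state, op) {
  compiled <- if (inherits(op, "pauli_op")) .compile_pauli(op) else op
  out <- complex(length(state))
  for (t in compiled) {
    v <- t$coeff * t$phase * state
    out[t$perm] <- out[t$perm] + v
  }
  out
}

#' Dense matrix of a Pauli operator
#' @param op a `pauli_op`.
#' @return complex `2^n x 2^n` matrix in the computational basis.
#' @export
pauli_to_matrix <- function(op) {
  dim <- 2^op$n_qubits
  M <- matrix(0 + 0i, dim, dim)
  b <- 0:(dim - 1)
  for (t in .compile_pauli(op)) {
    M[cbind(t$perm, b + 1L)] <- M[cbind(t$perm, b + 1L)] + t$coeff * t$phase
  }
  M
}
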