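# Ansatz circuits: k-UpCCGSD and GateFabric, simulated as exact statevectors
# with analytic (adjoint-mode) gradients.
#
# Fixed conventions (they change the circuit, so they are frozen here):
# * k-UpCCGSD layer ordering: all generalized spin-conserving singles in
#   lexicographic order of the spatial pair (p, q), alpha gate before beta
#   gate, followed by all paired doubles in lexicographic (p, q) order; each
#   layer carries its own parameters.
# * Givens sign convention: a gate with generator G = a+_to a_from - h.c.
#   (or its paired-double analogue) applies exp(theta * G).
# * GateFabric tile = paired-double rotation (theta) followed by an orbital
#   rotation (phi; alpha and beta Givens rotations sharing phi).  At zero
#   parameters every tile is the identity, so theta = 0 prepares exactly the
#   Hartree-Fock reference ("include identity block" convention).

.make_gate <- function(G, param, label) {
  list(G = G, G2 = G %*% G, param = param, label = label)
}

#' Build a k-UpCCGSD circuit
#'
#' `k` repeated layers, each containing all generalized spin-conserving single
#' excitations (one parameter per spin-orbital pair) and all paired double
#' excitations (pair `p alpha, p beta -> q alpha, q beta`, one parameter per
#' spatial pair).
#'
#' @param active an `active_space`.
#' @param k number of layers (>= 1).
#' @return an `ansatz_circuit`.
#' @export
build_kupccgsd <- function(active, k = 1L) {
  if (k < 1) stop("k must be >= 1")
  n_act <- active$n_active_orbitals
  n <- active$n_qubits
  gates <- list()
  excitations <- character(0)
  param <- 0L
  pairs <- if (n_act >= 2) combn(n_act, 2) else matrix(numeric(0), 2, 0)
  for (layer in seq_len(k)) {
    for (j in seq_len(ncol(pairs))) {
      p <- pairs[1, j]; q <- pairs[2, j]
      for (s in 0:1) {
        param <- param + 1L
        gates[[length(gates) + 1]] <- .make_gate(
          .single_excitation_generator(spin_orbital_qubit(p, s),
                                       spin_orbital_qubit(q, s), n),
          param,
          sprintf("L%d single %d%s->%d%s", layer, p, c("a", "b")[s + 1],
                  q, c("a", "b")[s + 1]))
        excitations <- c(excitations, tail(gates, 1)[[1]]$label)
      }
    }
    for (j in seq_len(ncol(pairs))) {
      p <- pairs[1, j]; q <- pairs[2, j]
      param <- param + 1L
      gates[[length(gates) + 1]] <- .make_gate(
        .paired_double_generator(p, q, n), param,
        sprintf("L%d paired-double %d%d->%d%d", layer, p, p, q, q))
      excitations <- c(excitations, tail(gates, 1)[[1]]$label)
    }
  }
  structure(list(kind = "kupccgsd", n_qubits = n, layers = as.integer(k),
                 parameter_count = param, gates = gates,
                 excitation_list = excitations,
                 reference_state = hf_reference_state(active),
                 n_electrons = active$n_active_electrons),
            class = "ansatz_circuit")
}

#' Build a GateFabric circuit
#'
#' Brick-wall tiling of 4-qubit tiles over `layers` layers.  Each tile spans
#' two adjacent spatial orbitals (four adjacent qubits) and applies a paired
#' double-excitation rotation followed by an orbital rotation; 2 parameters
#' per tile.  Odd layers start tiles at qubit 0, even layers at qubit 2
#' (brick offset); with exactly 4 qubits every layer holds one tile.
#' Particle number and spin are preserved by construction.
#'
#' @param active an `active_space`.
#' @param layers number of layers (>= 1).
#' @return an `ansatz_circuit`.
#' @export
build_gatefabric <- function(active, layers = 1L) {
  n <- active$n_qubits
  if (n < 4 || n %% 2 != 0) stop("GateFabric needs an even number >= 4 of qubits")
  if (layers < 1) stop("layers must be >= 1")
  n_act <- active$n_active_orbitals
  gates <- list()
  tiles <- character(0)
  param <- 0L
  for (layer in seq_len(layers)) {
    starts <- if (n_act == 2) 1L else {
      if (layer %% 2 == 1) seq(1L, n_act - 1L, by = 2L)
      else seq(2L, n_act - 1L, by = 2L)
    }
    starts <- starts[starts + 1 <= n_act]
    for (p in starts) {
      q <- p + 1L
      param_d <- param + 1L
      param_o <- param + 2L
      param <- param + 2L
      gates[[length(gates) + 1]] <- .make_gate(
        .paired_double_generator(p, q, n), param_d,
        sprintf("L%d tile q%d-%d double", layer, 2 * (p - 1), 2 * q - 1))
      for (s in 0:1) {
        gates[[length(gates) + 1]] <- .make_gate(
          .single_excitation_generator(spin_orbital_qubit(p, s),
                                       spin_orbital_qubit(q, s), n),
          param_o,
          sprintf("L%d tile q%d-%d orbrot %s", layer, 2 * (p - 1), 2 * q - 1,
                  c("a", "b")[s + 1]))
      }
      tiles <- c(tiles, sprintf("L%d tile spatial (%d,%d)", layer, p, q))
    }
  }
  structure(list(kind = "gatefabric", n_qubits = n, layers = as.integer(layers),
                 parameter_count = param, gates = gates,
                 excitation_list = tiles,
                 reference_state = hf_reference_state(active),
                 n_electrons = active$n_active_electrons),
            class = "ansatz_circuit")
}

#' @export
print.ansatz_circuit <- function(x, ...) {
  cat(sprintf("<%s circuit: %d qubits, %d layer(s), %d gates, %d parameters>\n",
              x$kind, x$n_qubits, x$layers, length(x$gates),
              x$parameter_count))
  invisible(x)
}

#' Prepare the ansatz state
#'
#' Applies the circuit gates to the Hartree-Fock reference.  Deterministic;
#' at `theta = 0` the prepared state is exactly the reference.
#'
#' @param circuit an `ansatz_circuit`.
#' @param theta parameter vector of length `parameter_count`.
#' @return complex statevector.
#' @export
prepare_state <- function(circuit, theta) {
  if (length(theta) != circuit$parameter_count) {
    stop(sprintf("theta has length %d; circuit expects %d", length(theta),
                 circuit$parameter_count))
  }
  v <- circuit$reference_state
  for (g in circuit$gates) {
    v <- .apply_givens(v, g$G, g$G2, theta[g$param])
  }
  v
}

# Adjoint-mode gradient of <psi(theta)| M |psi(theta)> for a real symmetric
# observable matrix M (dense or sparse).  Exact and deterministic.
.adjoint_gradient <- function(circuit, theta, M, state = NULL) {
  if (is.null(state)) state <- prepare_state(circuit, theta)
  lambda <- if (is.complex(M)) as.vector(M %*% state) else .smv(M, state)
  value <- Re(sum(Conj(state) * lambda))
  grad <- numeric(circuit$parameter_count)
  psi <- state
  for (i in rev(seq_along(circuit$gates))) {
    g <- circuit$gates[[i]]
    th <- theta[g$param]
    psi <- .apply_givens(psi, g$G, g$G2, -th)   # psi_{i-1}
    dv <- .apply_givens_deriv(psi, g$G, g$G2, th)
    grad[g$param] <- grad[g$param] + 2 * Re(sum(Conj(lambda) * dv))
    lambda <- .apply_givens(lambda, g$G, g$G2, -th)
  }
  list(value = value, gradient = grad, state = state)
}

#' Energy and exact gradient of the ansatz state
#'
#' `E = <psi(theta)|H|psi(theta)>` with the exact analytic gradient computed
#' by adjoint-mode differentiation of the statevector.
#'
#' @param circuit an `ansatz_circuit`.
#' @param theta parameter vector.
#' @param H the qubit Hamiltonian: a `pauli_op` or a (sparse or dense real
#'   symmetric) matrix in the computational basis.
#' @return list with `energy` (Hartree) and `gradient`.
#' @export
energy_and_gradient <- function(circuit, theta, H) {
  M <- if (inherits(H, "pauli_op")) {
    Hm <- pauli_to_matrix(H)
    if (max(abs(Im(Hm))) > 1e-10) stop("Hamiltonian matrix is not real")
    Re(Hm)
  } else H
  res <- .adjoint_gradient(circuit, theta, M)
  list(energy = res$value, gradient = res$gradient)
}

#' Export a circuit as a JSON gate list
#'
#' One record per gate: gate label, generator kind and 1-based parameter
#' index, for inspection and regression snapshots.
#'
#' @param circuit an `ansatz_circuit`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @export
circuit_to_json <- function(circuit, path = NULL) {
  recs <- lapply(circuit$gates, function(g) {
    list(label = g$label, param_index = g$param)
  })
  js <- jsonlite::toJSON(list(kind = circuit$kind, n_qubits = circuit$n_qubits,
                              layers = circuit$layers,
                              parameter_count = circuit$parameter_count,
                              gates = recs), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
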