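# 1-RDM measurement, spin summation, and embedding into the HF density.

#' Precompute the 1-RDM measurement plan
#'
#' Compiles the Hermitian measurement operators for every upper-triangle
#' element of the spin-orbital 1-RDM so repeated measurements inside an
#' optimization loop are cheap.
#'
#' @param n_qubits number of active spin orbitals (= qubits).
#' @return opaque plan consumed by [measure_active_rdm()].
#' @export
rdm_measurement_plan <- function(n_qubits) {
  plan <- list()
  for (p in 0:(n_qubits - 1)) for (q in p:(n_qubits - 1)) {
    ops <- jw_excitation_operator(p, q, n_qubits)
    plan[[length(plan) + 1]] <- list(
      p = p, q = q,
      re = .compile_pauli(ops$re),
      im = if (length(ops$im$terms) > 0) .compile_pauli(ops$im) else NULL)
  }
  structure(list(n_qubits = n_qubits, elements = plan),
            class = "rdm_plan")
}

#' Measure the active-space 1-RDM from a statevector
#'
#' Upper-triangle elements are obtained as expectation values of the
#' Hermitian operator pairs of [jw_excitation_operator()]; the lower triangle
#' is completed by Hermitian conjugation, so the result is Hermitian by
#' construction.
#'
#' @param state normalized statevector over the active qubits.
#' @param plan optional precompiled plan from [rdm_measurement_plan()].
#' @return an `active_rdm`: complex Hermitian matrix `D[pq] = <a+_p a_q>`
#'   over active spin orbitals.
#' @export
measure_active_rdm <- function(state, plan = NULL) {
  n <- .state_n_qubits(state)
  nrm <- sqrt(sum(Mod(state)^2))
  if (abs(nrm - 1) > 1e-8) stop("state is not normalized")
  if (is.null(plan)) plan <- rdm_measurement_plan(n)
  if (plan$n_qubits != n) stop("plan/state dimension mismatch")
  D <- matrix(0 + 0i, n, n)
  for (el in plan$elements) {
    re <- pauli_expectation(state, el$re)
    im <- if (is.null(el$im)) 0 else pauli_expectation(state, el$im)
    D[el$p + 1, el$q + 1] <- complex(real = re, imaginary = im)
    if (el$p != el$q) D[el$q + 1, el$p + 1] <- complex(real = re,
                                                       imaginary = -im)
  }
  structure(D, class = c("active_rdm", class(D)))
}

#' Spin-sum a spin-orbital 1-RDM to a spatial 1-RDM
#'
#' `D_spatial[p, q] = D[p alpha, q alpha] + D[p beta, q beta]` (interleaved
#' ordering; alpha-beta cross blocks are never read).  The imaginary residue
#' after summation must be below `imag_tol`; a larger residue signals a state
#' outside the real-representable class and raises an error.
#'
#' @param d an `active_rdm` (complex Hermitian, spin-orbital basis).
#' @param imag_tol tolerance on the imaginary residue.
#' @return real symmetric matrix over active spatial orbitals.
#' @export
spin_sum <- function(d, imag_tol = 1e-8) {
  n_so <- nrow(d)
  if (n_so %% 2 != 0) stop("spin-orbital RDM must have even dimension")
  n_act <- n_so %/% 2
  a <- seq(1, n_so, by = 2)
  b <- seq(2, n_so, by = 2)
  ds <- d[a, a, drop = FALSE] + d[b, b, drop = FALSE]
  resid <- max(abs(Im(ds)))
  if (resid > imag_tol) {
    stop(sprintf("imaginary residue %.3e above tolerance %.1e in spin_sum",
                 resid, imag_tol))
  }
  matrix(Re(ds), n_act, n_act)
}

#' Embed an active-space spatial 1-RDM into the full AO density
#'
#' Builds the full-MO density with 2 on the frozen-occupied diagonal, the
#' active-space matrix on the active block and 0 elsewhere (virtual-virtual
#' correlation outside the window is not assigned), then transforms
#' `gamma = C D_MO C^T` to the AO basis.
#'
#' @param d spatial active 1-RDM (n_act x n_act, real).
#' @param scf an `scf_reference`.
#' @param active the `active_space` used for the calculation.
#' @return AO density matrix `gamma` (nao x nao) for the full molecule.
#' @export
embed_active_rdm <- function(d, scf, active) {
  n_mo <- ncol(scf$mo_coefficients)
  if (nrow(d) != active$n_active_orbitals) stop("active RDM dimension mismatch")
  D_mo <- matrix(0, n_mo, n_mo)
  fr <- active$frozen_occupied_indices
  if (length(fr) > 0) diag(D_mo)[fr] <- 2
  ac <- active$active_mo_indices
  D_mo[ac, ac] <- d
  C <- scf$mo_coefficients
  C %*% D_mo %*% t(C)
}
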