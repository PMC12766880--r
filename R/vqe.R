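# The three optimization loops: plain VQE (energy-only convergence), VQE*
# (dual energy + 1-RDM convergence criterion) and VQE-LD (density-augmented
# loss L = E + w_D * DeltaD with exact gradients).

#' RMSD between consecutive 1-RDMs
#'
#' `DeltaD = sqrt( (1/N^2) * sum_pq |D_pq(n) - D_pq(n-1)|^2 )` where `N` is
#' the matrix dimension (number of active orbitals: spatial by default, spin
#' orbitals when the spin-orbital matrices are passed).
#'
#' @param d_now,d_prev equally sized 1-RDM matrices.
#' @return dimensionless scalar >= 0.
#' @export
delta_d <- function(d_now, d_prev) {
  if (!all(dim(d_now) == dim(d_prev))) stop("RDM shape mismatch")
  N <- nrow(d_now)
  sqrt(sum(Mod(d_now - d_prev)^2) / N^2)
}

#' Gradient-balancing weight for the density term
#'
#' `w_D = f * ||G_E|| / ||G_D||`, the ratio of gradient norms scaled by the
#' learning-rate factor `f`; returns 0 when `||G_D|| = 0` (first iteration
#' rule: the density gradient is defined as zero before a predecessor RDM
#' exists).
#'
#' @param grad_e,grad_d gradient vectors of equal length.
#' @param f non-negative scale factor.
#' @export
weight_wd <- function(grad_e, grad_d, f) {
  if (length(grad_e) != length(grad_d)) stop("gradient length mismatch")
  nd <- sqrt(sum(grad_d^2))
  if (nd == 0) return(0)
  f * sqrt(sum(grad_e^2)) / nd
}

# Observable matrix for the DeltaD gradient: A = sum_pq diff[pq] E_pq with
# diff = D(theta) - D_prev frozen at the current point; then
# grad DeltaD = grad <A> / (2 * DeltaD * N^2) ... see loss_and_gradient.
.delta_d_observable <- function(diff, e_pq_mats) {
  n <- nrow(diff)
  A <- NULL
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (abs(diff[p, q]) < 1e-300) next
    term <- diff[p, q] * e_pq_mats[[(p - 1) * n + q]]
    A <- if (is.null(A)) term else A + term
  }
  if (is.null(A)) e_pq_mats[[1]] * 0 else A
}

.spatial_e_pq_mats <- function(n_act, n_qubits) {
  mats <- vector("list", n_act * n_act)
  for (p in seq_len(n_act)) for (q in seq_len(n_act)) {
    mats[[(p - 1) * n_act + q]] <- .spatial_excitation_matrix(p, q, n_qubits)
  }
  mats
}

#' Density-augmented loss and its exact gradient
#'
#' Evaluates `L(theta) = E(theta) + w_D * DeltaD(theta)` and
#' `grad L = G_E + w_D * G_D`, with the previous-iteration RDM treated as a
#' constant reference.  `G_D` is obtained by exact adjoint differentiation
#' through the state preparation and the RDM measurement; at the
#' non-differentiable point `DeltaD = 0` (below 1e-14) the safeguarded
#' subgradient `G_D = 0` is used.
#'
#' @param circuit an `ansatz_circuit`.
#' @param theta parameter vector.
#' @param H qubit Hamiltonian (`pauli_op` or real matrix).
#' @param d_prev previous spatial 1-RDM (constant reference).
#' @param f learning-rate factor for `w_D`.
#' @param context optional precomputed context from [vqe_context()].
#' @return list with `loss`, `gradient`, `energy`, `delta_d`, `w_d`,
#'   `grad_e`, `grad_d`, `rdm` (current spatial 1-RDM).
#' @export
loss_and_gradient <- function(circuit, theta, H, d_prev, f,
                              context = NULL) {
  if (is.null(context)) context <- vqe_context(circuit, H)
  state <- prepare_state(circuit, theta)
  eres <- .adjoint_gradient(circuit, theta, context$H_mat, state = state)
  d_so <- measure_active_rdm(state, context$rdm_plan)
  d_sp <- spin_sum(d_so)
  n_act <- nrow(d_sp)

  dd <- delta_d(d_sp, d_prev)
  if (dd < 1e-14) {
    grad_d <- numeric(circuit$parameter_count)
  } else {
    A <- .delta_d_observable(d_sp - d_prev, context$e_pq_mats)
    ares <- .adjoint_gradient(circuit, theta, A, state = state)
    # DeltaD = sqrt(S)/N with S = sum |D - D_prev|^2:
    # dDeltaD = dS / (2 DeltaD N^2) and dS = 2 d<A>, so dDeltaD = d<A>/(DeltaD N^2)
    grad_d <- ares$gradient / (dd * n_act^2)
  }
  w_d <- weight_wd(eres$gradient, grad_d, f)
  list(loss = eres$value + w_d * dd,
       gradient = eres$gradient + w_d * grad_d,
       energy = eres$value, delta_d = dd, w_d = w_d,
       grad_e = eres$gradient, grad_d = grad_d, rdm = d_sp,
       rdm_spin_orbital = d_so, state = state)
}

#' Precompute the reusable pieces of a VQE run
#'
#' Hamiltonian matrix, compiled RDM measurement plan and spin-summed
#' excitation-operator matrices for the `DeltaD` gradient.
#'
#' @param circuit an `ansatz_circuit`.
#' @param H qubit Hamiltonian (`pauli_op` or real matrix).
#' @export
vqe_context <- function(circuit, H) {
  H_mat <- if (inherits(H, "pauli_op")) {
    Hm <- pauli_to_matrix(H)
    if (max(abs(Im(Hm))) > 1e-10) stop("Hamiltonian matrix is not real")
    Re(Hm)
  } else H
  n_qubits <- circuit$n_qubits
  list(H_mat = H_mat,
       rdm_plan = rdm_measurement_plan(n_qubits),
       e_pq_mats = .spatial_e_pq_mats(n_qubits %/% 2, n_qubits))
}

#' Convergence settings for a VQE run
#'
#' @param e_tol energy convergence threshold `E_tol` (Hartree).
#' @param d_tol 1-RDM RMSD convergence threshold `D_tol` (dimensionless).
#' @param learning_rate gradient-descent step size.
#' @param f learning-rate factor for the `w_D` weight (VQE-LD only).
#' @param max_iterations iteration cap; reaching it flags the result
#'   non-converged instead of raising an error.
#' @param delta_d_basis `"spatial"` (default) computes `DeltaD` on the
#'   spin-summed spatial RDM; `"spin"` uses the spin-orbital matrix.
#' @export
convergence_settings <- function(e_tol = 1e-6, d_tol = 1e-6,
                                 learning_rate = 0.4, f = 0.05,
                                 max_iterations = 5000L,
                                 delta_d_basis = c("spatial", "spin")) {
  stopifnot(e_tol > 0, d_tol > 0, learning_rate > 0, f >= 0)
  list(e_tol = e_tol, d_tol = d_tol, learning_rate = learning_rate, f = f,
       max_iterations = as.integer(max_iterations),
       delta_d_basis = match.arg(delta_d_basis))
}

#' Run a VQE optimization
#'
#' Deterministic full-batch gradient descent from `theta = 0` (the
#' Hartree-Fock reference) with fixed step size.  Exit criteria per variant:
#' `vqe` stops when `|Delta E| < e_tol`; `vqe_star` when additionally
#' `DeltaD < d_tol` on the same iteration; `vqe_ld` uses the same dual
#' criterion but drives the update with the gradient of the augmented loss
#' `L = E + w_D * DeltaD`.  The first iteration never terminates (no
#' predecessor) and uses `w_D = 0`.
#'
#' @param variant one of `"vqe"`, `"vqe_star"`, `"vqe_ld"`.
#' @param circuit an `ansatz_circuit`.
#' @param H qubit Hamiltonian (`pauli_op` or real symmetric matrix).
#' @param settings a [convergence_settings()] list.
#' @return a `vqe_result` with `final_theta`, `final_energy`,
#'   `final_active_rdm` (spin-orbital), `final_spatial_rdm`, `trajectory`
#'   (one row per iteration), `converged`, `steps`, `variant`.
#' @export
run_vqe <- function(variant = c("vqe", "vqe_star", "vqe_ld"), circuit, H,
                    settings = convergence_settings()) {
  variant <- match.arg(variant)
  ctx <- vqe_context(circuit, H)
  lr <- settings$learning_rate
  theta <- numeric(circuit$parameter_count)
  d_prev <- NULL
  e_prev <- NA_real_
  spatial <- settings$delta_d_basis == "spatial"
  traj <- vector("list", 64)
  thetas <- vector("list", 64)
  nrec <- 0L
  converged <- FALSE

  for (it in seq_len(settings$max_iterations)) {
    state <- prepare_state(circuit, theta)
    eres <- .adjoint_gradient(circuit, theta, ctx$H_mat, state = state)
    d_so <- measure_active_rdm(state, ctx$rdm_plan)
    d_sp <- spin_sum(d_so)
    d_cur <- if (spatial) d_sp else d_so
    n_dim <- nrow(d_cur)

    dd <- if (is.null(d_prev)) NA_real_ else delta_d(d_cur, d_prev)
    grad_d <- numeric(circuit$parameter_count)
    w_d <- 0
    if (variant == "vqe_ld" && !is.null(d_prev) && !is.na(dd) && dd >= 1e-14) {
      diffm <- d_cur - d_prev
      A <- if (spatial) .delta_d_observable(diffm, ctx$e_pq_mats) else
        .delta_d_observable_spin(diffm, circuit$n_qubits)
      ares <- .adjoint_gradient(circuit, theta, A, state = state)
      grad_d <- ares$gradient / (dd * n_dim^2)
      w_d <- weight_wd(eres$gradient, grad_d, settings$f)
    }
    loss <- eres$value + if (is.na(dd)) 0 else w_d * dd
    delta_e <- if (is.na(e_prev)) NA_real_ else abs(eres$value - e_prev)

    nrec <- nrec + 1L
    if (nrec > length(traj)) {
      traj <- c(traj, vector("list", length(traj)))
      thetas <- c(thetas, vector("list", length(thetas)))
    }
    thetas[[nrec]] <- theta
    traj[[nrec]] <- data.frame(
      n = it, energy = eres$value, delta_e = delta_e, delta_d = dd,
      w_d = w_d, grad_e_norm = sqrt(sum(eres$gradient^2)),
      grad_d_norm = sqrt(sum(grad_d^2)), loss = loss)

    if (!is.na(delta_e)) {
      hit <- switch(variant,
        vqe = delta_e < settings$e_tol,
        vqe_star = delta_e < settings$e_tol && dd < settings$d_tol,
        vqe_ld = delta_e < settings$e_tol && dd < settings$d_tol)
      if (hit) { converged <- TRUE; break }
    }

    update <- if (variant == "vqe_ld") eres$gradient + w_d * grad_d
              else eres$gradient
    theta <- theta - lr * update
    d_prev <- d_cur
    e_prev <- eres$value
  }

  trajectory <- do.call(rbind, traj[seq_len(nrec)])
  theta_final <- thetas[[nrec]]   # parameters of the last recorded iteration
  last_state <- prepare_state(circuit, theta_final)
  d_so <- measure_active_rdm(last_state, ctx$rdm_plan)
  structure(list(final_theta = theta_final,
                 theta_snapshots = thetas[seq_len(nrec)],
                 final_energy = trajectory$energy[nrec],
                 final_active_rdm = d_so,
                 final_spatial_rdm = spin_sum(d_so),
                 trajectory = trajectory,
                 converged = converged,
                 steps = trajectory$n[nrec],
                 variant = variant,
                 settings = settings), class = "vqe_result")
}

# spin-orbital variant of the DeltaD observable (config switch)
.delta_d_observable_spin <- function(diff, n_qubits) {
  A <- NULL
  for (p in seq_len(n_qubits)) for (q in seq_len(n_qubits)) {
    w <- diff[p, q]
    if (Mod(w) < 1e-300) next
    term <- Re(w) * ladder_operator_matrix(c(p - 1, q - 1), c(TRUE, FALSE),
                                           n_qubits)
    A <- if (is.null(A)) term else A + term
  }
  # Hermitian input guarantees the imaginary parts cancel pairwise; the
  # real-generator circuits used here produce real RDMs anyway.
  A
}

#' @export
print.vqe_result <- function(x, ...) {
  cat(sprintf("<%s: E = %.10f Eh after %d steps (%s)>\n", x$variant,
              x$final_energy, x$steps,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
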