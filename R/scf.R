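# Integral provider and restricted Hartree-Fock.
#
# The mathematical core only consumes an SCFReference; the provider below
# (in-package McMurchie-Davidson engine) can be swapped for any object with
# the same fields, and references can be serialized/reloaded from disk.

#' Compute all AO integrals for a geometry (integral-provider contract)
#'
#' @param geom a `vqerdm_geometry`.
#' @param basis basis set name.
#' @param origin gauge origin (Bohr) for the dipole integrals.
#' @return list with `S`, `T`, `V`, `hcore`, `eri` (chemists' convention,
#'   nao^4 array), `dipole` (list of three nao x nao matrices), the basis
#'   description and the nuclear repulsion energy.
#' @export
compute_integrals <- function(geom, basis = "sto-3g", origin = c(0, 0, 0)) {
  bs <- build_basis(geom, basis)
  coords_bohr <- angstrom_to_bohr(geom$coords)
  one <- cpp_one_electron(bs$shells, as.numeric(geom$Z), coords_bohr,
                          as.numeric(origin))
  eri <- cpp_eri(bs$shells)
  list(S = one$S, T = one$T, V = one$V, hcore = one$T + one$V, eri = eri,
       dipole = list(x = one$DX, y = one$DY, z = one$DZ),
       dipole_origin = origin, basis = bs, e_nuc = nuclear_repulsion(geom))
}

# eigen() sorts decreasing; orbital logic everywhere wants ascending energies
.eig_ascending <- function(M) {
  es <- eigen(M, symmetric = TRUE)
  idx <- order(es$values)
  list(values = es$values[idx], vectors = es$vectors[, idx, drop = FALSE])
}

.coulomb_exchange <- function(eri, D) {
  n <- dim(eri)[1]
  g2 <- matrix(eri, n * n, n * n)           # (mu nu | la si)
  J <- matrix(g2 %*% as.vector(D), n, n)
  gk <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)  # (mu la | nu si)
  K <- matrix(gk %*% as.vector(D), n, n)
  list(J = J, K = K)
}

#' Restricted Hartree-Fock
#'
#' Converges a closed-shell RHF reference with DIIS acceleration.  The SCF is
#' considered converged when the energy change falls below `e_conv` and the
#' DIIS error norm below `err_conv`.
#'
#' @param geom a `vqerdm_geometry` with multiplicity 1.
#' @param basis basis set name.
#' @param e_conv,err_conv convergence thresholds (Hartree; error norm).
#' @param max_iter iteration cap.
#' @return An `scf_reference` with fields `mo_coefficients`, `overlap`,
#'   `core_hamiltonian`, `eri`, `dipole_integrals`, `orbital_energies`,
#'   `hf_energy`, `hf_density_ao`, `e_nuc`, `n_electrons`, `geometry`, `basis`.
#' @export
run_scf <- function(geom, basis = "sto-3g", e_conv = 1e-12, err_conv = 1e-10,
                    max_iter = 300L) {
  if (geom$multiplicity != 1L) {
    stop("run_scf implements closed-shell RHF only (multiplicity 1)")
  }
  ints <- compute_integrals(geom, basis)
  n_elec <- n_electrons(geom)
  if (n_elec %% 2 != 0) stop("odd electron count in a closed-shell SCF")
  nocc <- n_elec %/% 2
  S <- ints$S
  h <- ints$hcore
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) stop("overlap matrix not positive definite")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)

  # core guess
  Fp <- t(X) %*% h %*% X
  ef <- .eig_ascending(Fp)
  C <- X %*% ef$vectors
  D <- 2 * C[, seq_len(nocc), drop = FALSE] %*% t(C[, seq_len(nocc), drop = FALSE])

  e_old <- Inf
  diis_F <- list(); diis_err <- list()
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    jk <- .coulomb_exchange(ints$eri, D)
    Fm <- h + jk$J - 0.5 * jk$K
    e_elec <- 0.5 * sum(D * (h + Fm))
    e_tot <- e_elec + ints$e_nuc
    trace <- c(trace, e_tot)

    err <- Fm %*% D %*% S - S %*% D %*% Fm
    err <- t(X) %*% err %*% X
    err_norm <- sqrt(sum(err^2))
    if (abs(e_tot - e_old) < e_conv && err_norm < err_conv && it > 1) {
      ef <- .eig_ascending(t(X) %*% Fm %*% X)
      C <- X %*% ef$vectors
      # deterministic sign convention: largest-|coefficient| entry positive
      for (k in seq_len(ncol(C))) {
        j <- which.max(abs(C[, k]))
        if (C[j, k] < 0) C[, k] <- -C[, k]
      }
      D <- 2 * C[, seq_len(nocc), drop = FALSE] %*%
        t(C[, seq_len(nocc), drop = FALSE])
      return(structure(list(
        mo_coefficients = C, overlap = S, core_hamiltonian = h,
        eri = ints$eri, dipole_integrals = ints$dipole,
        dipole_origin = ints$dipole_origin,
        orbital_energies = ef$values, hf_energy = e_tot,
        hf_density_ao = D, e_nuc = ints$e_nuc, n_electrons = n_elec,
        n_occupied = nocc, geometry = geom, basis = ints$basis,
        scf_iterations = it), class = "scf_reference"))
    }
    e_old <- e_tot

    diis_F[[length(diis_F) + 1]] <- Fm
    diis_err[[length(diis_err) + 1]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_err <- diis_err[-1] }
    m <- length(diis_F)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m)) {
        B[i, j] <- sum(diis_err[[i]] * diis_err[[j]])
      }
      B[m + 1, seq_len(m)] <- -1; B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) {
        Fm <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
    ef <- .eig_ascending(t(X) %*% Fm %*% X)
    C <- X %*% ef$vectors
    D <- 2 * C[, seq_len(nocc), drop = FALSE] %*%
      t(C[, seq_len(nocc), drop = FALSE])
  }
  stop(paste0("SCF failed to converge in ", max_iter, " iterations; ",
              "energy trace: ",
              paste(sprintf("%.10f", tail(trace, 6)), collapse = ", ")))
}

#' @export
print.scf_reference <- function(x, ...) {
  cat(sprintf("<RHF/%s reference: %d AOs, %d electrons, E = %.10f Eh (%d iterations)>\n",
              "STO-3G", nrow(x$overlap), x$n_electrons, x$hf_energy,
              x$scf_iterations))
  invisible(x)
}

#' Save / load an SCF reference
#'
#' Single-file container with all named arrays of the reference, so the
#' mathematical core can be exercised without rerunning the integral engine.
#'
#' @param scf an `scf_reference`.
#' @param path file path.
#' @export
scf_save <- function(scf, path) { saveRDS(scf, path); invisible(path) }

#' @rdname scf_save
#' @export
scf_load <- function(path) readRDS(path)
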