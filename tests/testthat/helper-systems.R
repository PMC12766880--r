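# Shared fixtures and independent oracles.  Heavy objects are memoized in a
# session-level cache so the acceptance tests and the per-module tests reuse
# the same converged runs.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture_system <- function(name, n_e, n_o, ansatz = list(kind = "kupccgsd", k = 1L)) {
  key <- paste("sys", name, n_e, n_o, ansatz$kind,
               ansatz$k %||% ansatz$layers, sep = "_")
  cached(key, {
    geom <- make_fixture(name)$geometry
    # h3plus (2,2) legitimately warns about its degenerate virtual edge;
    # that behaviour has its own test in test-molecular-system.R
    suppressWarnings(prepare_system(geom, n_e, n_o, ansatz))
  })
}

fixture_casci <- function(name, n_e, n_o) {
  key <- paste("ci", name, n_e, n_o, sep = "_")
  cached(key, solve_casci(fixture_system(name, n_e, n_o)$ham))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CH5+ studies are the heavy acceptance surface; one shared run per (R, ansatz)
ch5_cached_study <- function(R, kind = "kupccgsd", ...) {
  key <- sprintf("ch5_%s_%.1f", kind, R)
  cached(key, {
    ansatz <- if (kind == "kupccgsd") list(kind = "kupccgsd", k = 1L)
              else list(kind = "gatefabric", layers = 2L)
    ch5_study(R, ansatz = ansatz, ...)
  })
}

# --- independent oracles ----------------------------------------------------

# dense expectation <psi|M|psi> for a sparse/dense real matrix
dense_expect <- function(psi, M) {
  Re(sum(Conj(psi) * (as.matrix(M) %*% psi)))
}

# lowest eigenvalue of the JW Hamiltonian matrix restricted to the
# (N_alpha, N_beta) occupation sector -- independent of the Slater-Condon code
jw_sector_ground_energy <- function(pauli_ham, n_alpha, n_beta) {
  Hm <- pauli_to_matrix(pauli_ham)
  n <- pauli_ham$n_qubits
  w <- 2^(seq.int(n - 1, 0))
  b <- 0:(2^n - 1)
  na <- rowSums(outer(b, w[seq(1, n, 2)], function(x, y) bitwAnd(x, y) > 0))
  nb <- rowSums(outer(b, w[seq(2, n, 2)], function(x, y) bitwAnd(x, y) > 0))
  sel <- which(na == n_alpha & nb == n_beta)
  min(eigen(Re(Hm[sel, sel]), symmetric = TRUE)$values)
}

# spin-summed excitation operator built from the bit-arithmetic ladder
# matrices (a route independent of the Pauli-string algebra)
.spatial_ladder_pair <- function(p, q, nq) {
  ladder_operator_matrix(c(spin_orbital_qubit(p, 0), spin_orbital_qubit(q, 0)),
                         c(TRUE, FALSE), nq) +
    ladder_operator_matrix(c(spin_orbital_qubit(p, 1), spin_orbital_qubit(q, 1)),
                           c(TRUE, FALSE), nq)
}

# closed-form (ss|ss) contracted ERI (two-center Boys formula); oracle for
# the general integral engine on all-s systems
s_only_eri <- function(shells, i, j, k, l) {
  tot <- 0
  for (ii in seq_along(shells[[i]]$exponents))
    for (jj in seq_along(shells[[j]]$exponents))
      for (kk in seq_along(shells[[k]]$exponents))
        for (ll in seq_along(shells[[l]]$exponents)) {
          a <- shells[[i]]$exponents[ii]; b <- shells[[j]]$exponents[jj]
          cg <- shells[[k]]$exponents[kk]; d <- shells[[l]]$exponents[ll]
          A <- shells[[i]]$center; B <- shells[[j]]$center
          C <- shells[[k]]$center; D <- shells[[l]]$center
          p <- a + b; q <- cg + d
          P <- (a * A + b * B) / p; Q <- (cg * C + d * D) / q
          K <- exp(-a * b / p * sum((A - B)^2)) *
               exp(-cg * d / q * sum((C - D)^2))
          Tv <- p * q / (p + q) * sum((P - Q)^2)
          F0 <- if (Tv < 1e-13) 1 else
            0.5 * sqrt(pi / Tv) * 2 * pnorm(sqrt(2 * Tv)) - 0.5 * sqrt(pi / Tv)
          v <- 2 * pi^2.5 / (p * q * sqrt(p + q)) * K * F0
          cc <- shells[[i]]$coefficients[ii] * shells[[j]]$coefficients[jj] *
                shells[[k]]$coefficients[kk] * shells[[l]]$coefficients[ll]
          tot <- tot + cc * v
        }
  tot
}

# central finite-difference gradient of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# random number-conserving state on n qubits with n_occ occupied spin orbitals
random_sector_state <- function(n, n_occ, seed, complex_amp = TRUE) {
  set.seed(seed)
  pc <- vqerdm:::.popcount_table(n)
  sel <- which(pc == n_occ)
  psi <- complex(2^n)
  amp <- rnorm(length(sel))
  if (complex_amp) amp <- amp + 1i * rnorm(length(sel))
  psi[sel] <- amp
  psi / sqrt(sum(Mod(psi)^2))
}
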