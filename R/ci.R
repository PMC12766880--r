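# Determinant-based CASCI on a folded active-space Hamiltonian: the internal
# oracle for energies and 1-RDMs.  FCI is the all-orbitals-active case.
#
# Determinants are (alpha mask, beta mask) pairs over active spatial orbitals;
# orbital p (1-based) occupies bit p-1.  The fermionic phase convention places
# the full alpha string before the beta string in each determinant's operator
# ordering (verified against the dense Jordan-Wigner oracle in the tests).

.occ_orbitals <- function(mask, n) which(bitwAnd(mask, 2^(0:(n - 1))) > 0)

.mask_popcount <- function(mask) {
  n <- 0L
  while (mask > 0) { n <- n + bitwAnd(mask, 1L); mask <- bitwShiftR(mask, 1L) }
  n
}

# phase of a_p applied to mask (p occupied assumed): (-1)^(occupied below p)
.phase_below <- function(mask, p) {
  below <- bitwAnd(mask, 2^(p - 1) - 1)
  if (.mask_popcount(below) %% 2 == 0) 1 else -1
}

# sign and resulting mask of a+_a a_i on mask (i occupied, a unoccupied)
.apply_single <- function(mask, i, a) {
  s1 <- .phase_below(mask, i)
  m1 <- mask - 2^(i - 1)
  s2 <- .phase_below(m1, a)
  list(mask = m1 + 2^(a - 1), sign = s1 * s2)
}

#' Determinant basis for a CAS sector
#'
#' All determinants with fixed particle numbers `N_alpha = N_beta = n_e / 2`
#' over `n_act` spatial orbitals, in deterministic lexicographic order.
#'
#' @param n_act number of active spatial orbitals.
#' @param n_electrons number of active electrons (even, S_z = 0 sector).
#' @return list with `amask`, `bmask` integer vectors and `n_det`.
#' @export
determinant_basis <- function(n_act, n_electrons) {
  if (n_electrons %% 2 != 0) stop("only the S_z = 0 sector is supported")
  na <- n_electrons %/% 2
  if (na > n_act) stop("more electrons than orbitals in the active space")
  strings <- if (na == 0) 0L else
    apply(combn(n_act, na), 2, function(occ) sum(2^(occ - 1)))
  strings <- sort(as.integer(strings))
  grid <- expand.grid(b = strings, a = strings)   # alpha varies slower
  list(amask = as.integer(grid$a), bmask = as.integer(grid$b),
       n_det = length(strings)^2, n_act = n_act,
       n_electrons = as.integer(n_electrons))
}

# Slater-Condon matrix element between two determinants (spatial integrals,
# chemists' convention).  Returns 0 for excitation degree > 2.
.sc_element <- function(aI, bI, aJ, bJ, h, g, n) {
  da <- bitwXor(aI, aJ); db <- bitwXor(bI, bJ)
  dega <- .mask_popcount(da) %/% 2
  degb <- .mask_popcount(db) %/% 2
  deg <- dega + degb
  if (deg > 2) return(0)
  if (deg == 0) {
    occa <- .occ_orbitals(aI, n); occb <- .occ_orbitals(bI, n)
    e <- sum(diag(h)[occa]) + sum(diag(h)[occb])
    for (i in occa) for (j in occa) e <- e + 0.5 * (g[i, i, j, j] - g[i, j, j, i])
    for (i in occb) for (j in occb) e <- e + 0.5 * (g[i, i, j, j] - g[i, j, j, i])
    for (i in occa) for (j in occb) e <- e + g[i, i, j, j]
    return(e)
  }
  if (deg == 1) {
    if (dega == 1) {
      i <- .occ_orbitals(bitwAnd(da, aJ), n); a <- .occ_orbitals(bitwAnd(da, aI), n)
      ex <- .apply_single(aJ, i, a)
      occ_same <- .occ_orbitals(aJ, n); occ_other <- .occ_orbitals(bJ, n)
    } else {
      i <- .occ_orbitals(bitwAnd(db, bJ), n); a <- .occ_orbitals(bitwAnd(db, bI), n)
      ex <- .apply_single(bJ, i, a)
      occ_same <- .occ_orbitals(bJ, n); occ_other <- .occ_orbitals(aJ, n)
    }
    f <- h[a, i]
    for (j in setdiff(occ_same, i)) f <- f + g[a, i, j, j] - g[a, j, j, i]
    for (j in occ_other) f <- f + g[a, i, j, j]
    return(ex$sign * f)
  }
  # degree 2
  if (dega == 2 || degb == 2) {
    if (dega == 2) { mJ <- aJ; d <- da; mI <- aI } else { mJ <- bJ; d <- db; mI <- bI }
    ij <- .occ_orbitals(bitwAnd(d, mJ), n)   # occupied in J only (removed)
    ab <- .occ_orbitals(bitwAnd(d, mI), n)   # occupied in I only (added)
    i <- ij[1]; j <- ij[2]; a <- ab[1]; b <- ab[2]
    e1 <- .apply_single(mJ, i, a)
    e2 <- .apply_single(e1$mask, j, b)
    return(e1$sign * e2$sign * (g[a, i, b, j] - g[b, i, a, j]))
  }
  # alpha-beta double
  ia <- .occ_orbitals(bitwAnd(da, aJ), n); aa <- .occ_orbitals(bitwAnd(da, aI), n)
  ib <- .occ_orbitals(bitwAnd(db, bJ), n); ab <- .occ_orbitals(bitwAnd(db, bI), n)
  ea <- .apply_single(aJ, ia, aa)
  eb <- .apply_single(bJ, ib, ab)
  ea$sign * eb$sign * g[aa, ia, ab, ib]
}

# Dense CI Hamiltonian matrix (electronic part only).
.ci_matrix_dense <- function(basis, h, g) {
  nd <- basis$n_det; n <- basis$n_act
  H <- matrix(0, nd, nd)
  for (I in seq_len(nd)) {
    for (J in I:nd) {
      v <- .sc_element(basis$amask[I], basis$bmask[I],
                       basis$amask[J], basis$bmask[J], h, g, n)
      H[I, J] <- v; H[J, I] <- v
    }
  }
  H
}

# Sparse CI Hamiltonian via connected-excitation enumeration (used above the
# dense cutoff), followed by a Davidson solve for the lowest eigenpair.
.ci_matrix_sparse <- function(basis, h, g) {
  nd <- basis$n_det; n <- basis$n_act
  key <- paste(basis$amask, basis$bmask)
  index <- setNames(seq_len(nd), key)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(I, J, v) {
    if (abs(v) > 1e-14) { ii <<- c(ii, I); jj <<- c(jj, J); xx <<- c(xx, v) }
  }
  for (I in seq_len(nd)) {
    aI <- basis$amask[I]; bI <- basis$bmask[I]
    push(I, I, .sc_element(aI, bI, aI, bI, h, g, n))
    occa <- .occ_orbitals(aI, n); vira <- setdiff(seq_len(n), occa)
    occb <- .occ_orbitals(bI, n); virb <- setdiff(seq_len(n), occb)
    conn <- list()
    for (i in occa) for (a in vira)
      conn[[length(conn) + 1]] <- c(aI - 2^(i - 1) + 2^(a - 1), bI)
    for (i in occb) for (a in virb)
      conn[[length(conn) + 1]] <- c(aI, bI - 2^(i - 1) + 2^(a - 1))
    if (length(occa) >= 2 && length(vira) >= 2) {
      for (ij in asplit(combn(occa, 2), 2)) for (ab in asplit(combn(vira, 2), 2))
        conn[[length(conn) + 1]] <- c(aI - sum(2^(ij - 1)) + sum(2^(ab - 1)), bI)
    }
    if (length(occb) >= 2 && length(virb) >= 2) {
      for (ij in asplit(combn(occb, 2), 2)) for (ab in asplit(combn(virb, 2), 2))
        conn[[length(conn) + 1]] <- c(aI, bI - sum(2^(ij - 1)) + sum(2^(ab - 1)))
    }
    for (i in occa) for (a in vira) for (j in occb) for (b in virb)
      conn[[length(conn) + 1]] <- c(aI - 2^(i - 1) + 2^(a - 1),
                                    bI - 2^(j - 1) + 2^(b - 1))
    for (cj in conn) {
      J <- index[[paste(cj[1], cj[2])]]
      if (J > I) {
        v <- .sc_element(basis$amask[J], basis$bmask[J], aI, bI, h, g, n)
        push(I, J, v); push(J, I, v)
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nd, nd))
}

.davidson_lowest <- function(Hs, tol = 1e-10, max_iter = 200L) {
  nd <- nrow(Hs)
  dg <- Matrix::diag(Hs)
  v <- numeric(nd); v[which.min(dg)] <- 1
  V <- matrix(v, nd, 1)
  for (it in seq_len(max_iter)) {
    W <- as.matrix(Hs %*% V)
    Hred <- crossprod(V, W)
    es <- eigen(Hred, symmetric = TRUE)
    th <- es$values[length(es$values)]  # placeholder; take lowest below
    k <- which.min(es$values)
    th <- es$values[k]
    y <- es$vectors[, k]
    x <- V %*% y
    r <- W %*% y - th * x
    if (sqrt(sum(r^2)) < tol) {
      return(list(value = th, vector = as.vector(x)))
    }
    denom <- dg - th
    denom[abs(denom) < 1e-8] <- 1e-8
    t <- as.vector(r) / denom
    t <- t - V %*% crossprod(V, t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-14) return(list(value = th, vector = as.vector(x)))
    V <- cbind(V, t / nt)
    if (ncol(V) > 40) {  # restart
      V <- matrix(as.vector(x), nd, 1)
    }
  }
  stop("Davidson did not converge")
}

#' Solve CASCI for the lowest state
#'
#' Builds the Hamiltonian matrix over the `S_z = 0` determinant basis with the
#' Slater-Condon rules and takes the lowest eigenpair: dense diagonalization
#' up to `dense_cutoff` determinants, Davidson above.
#'
#' @param ham an `active_hamiltonian` (from [fold_frozen_core()] or
#'   [read_fcidump()]).
#' @param n_electrons number of active electrons; defaults to the value
#'   carried by `ham`.
#' @param dense_cutoff basis-size threshold between dense and iterative paths.
#' @return a `ci_result` with `energy` (total, includes `e_core`),
#'   `ci_vector`, `basis`, `one_rdm` (spatial) and `n_act`.
#' @export
solve_casci <- function(ham, n_electrons = ham$n_active_electrons,
                        dense_cutoff = 2000L) {
  n <- ham$n_active_orbitals
  basis <- determinant_basis(n, n_electrons)
  if (basis$n_det <= dense_cutoff) {
    H <- .ci_matrix_dense(basis, ham$h_eff, ham$g)
    es <- eigen(H, symmetric = TRUE)
    k <- which.min(es$values)
    val <- es$values[k]
    vec <- es$vectors[, k]
  } else {
    Hs <- .ci_matrix_sparse(basis, ham$h_eff, ham$g)
    sol <- .davidson_lowest(Hs)
    val <- sol$value
    vec <- sol$vector
  }
  vec <- vec / sqrt(sum(vec^2))
  # deterministic global sign: largest-|c| coefficient positive
  jmax <- which.max(abs(vec))
  if (vec[jmax] < 0) vec <- -vec
  res <- structure(list(energy = val + ham$e_core, electronic_energy = val,
                        ci_vector = vec, basis = basis, n_act = n,
                        n_electrons = n_electrons), class = "ci_result")
  res$one_rdm <- ci_one_rdm(res)
  res
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("<CASCI(%d,%d): %d determinants, E = %.10f Eh>\n",
              x$n_electrons, x$n_act, x$basis$n_det, x$energy))
  invisible(x)
}

#' Spatial 1-RDM of a CI wavefunction
#'
#' `D[pq] = sum_sigma <Psi| a+_{p sigma} a_{q sigma} |Psi>` accumulated over
#' determinant pairs connected by at most a single excitation, with
#' Slater-Condon phase factors.
#'
#' @param result a `ci_result`.
#' @return real symmetric matrix with trace `n_electrons`.
#' @export
ci_one_rdm <- function(result) {
  basis <- result$basis; c_ <- result$ci_vector; n <- result$n_act
  key <- paste(basis$amask, basis$bmask)
  index <- setNames(seq_len(basis$n_det), key)
  D <- matrix(0, n, n)
  for (J in seq_len(basis$n_det)) {
    aJ <- basis$amask[J]; bJ <- basis$bmask[J]
    occa <- .occ_orbitals(aJ, n); occb <- .occ_orbitals(bJ, n)
    for (p in occa) D[p, p] <- D[p, p] + c_[J]^2
    for (p in occb) D[p, p] <- D[p, p] + c_[J]^2
    for (q in occa) for (p in setdiff(seq_len(n), occa)) {
      ex <- .apply_single(aJ, q, p)
      I <- index[[paste(ex$mask, bJ)]]
      D[p, q] <- D[p, q] + ex$sign * c_[I] * c_[J]
    }
    for (q in occb) for (p in setdiff(seq_len(n), occb)) {
      ex <- .apply_single(bJ, q, p)
      I <- index[[paste(aJ, ex$mask)]]
      D[p, q] <- D[p, q] + ex$sign * c_[I] * c_[J]
    }
  }
  D
}

#' Load a CI wavefunction as a qubit statevector
#'
#' Maps each determinant to its Jordan-Wigner computational basis state
#' (interleaved spin-orbital ordering) including the fermionic reordering
#' phase between the determinant's alpha-then-beta operator ordering and the
#' ascending spin-orbital ordering of the qubit register.
#'
#' @param result a `ci_result`.
#' @return complex statevector of length `4^n_act`.
#' @export
ci_statevector <- function(result) {
  n <- result$n_act
  nq <- 2L * n
  w <- .qubit_weights(nq)
  v <- complex(2^nq)
  for (J in seq_len(result$basis$n_det)) {
    occa <- .occ_orbitals(result$basis$amask[J], n)
    occb <- .occ_orbitals(result$basis$bmask[J], n)
    so <- c(spin_orbital_qubit(occa, 0), spin_orbital_qubit(occb, 1))
    # parity of the permutation sorting the creation-operator list
    inv <- 0L
    if (length(so) > 1) {
      for (i in seq_len(length(so) - 1)) {
        inv <- inv + sum(so[(i + 1):length(so)] < so[i])
      }
    }
    idx <- sum(w[so + 1]) + 1
    v[idx] <- v[idx] + result$ci_vector[J] * (-1)^inv
  }
  v
}
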