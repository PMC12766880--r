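# Frozen-core folding into an active-space second-quantized Hamiltonian,
# plus FCIDUMP I/O so the same folded integrals feed both the VQE stack and
# the determinant CI reference bit-identically.

.ao_to_mo_1e <- function(h_ao, C) t(C) %*% h_ao %*% C

.ao_to_mo_2e <- function(eri_ao, C) {
  n <- dim(eri_ao)[1]
  m <- ncol(C)
  # sequential quarter transforms, chemists' convention (ij|kl)
  g <- eri_ao
  g <- array(t(C) %*% matrix(g, n, n^3), c(m, n, n, n))
  g <- aperm(g, c(2, 3, 4, 1))                  # nu la si p
  g <- array(t(C) %*% matrix(g, n, n^2 * m), c(m, n, n, m))
  g <- aperm(g, c(2, 3, 4, 1))                  # la si p q
  g <- array(t(C) %*% matrix(g, n, n * m^2), c(m, n, m, m))
  g <- aperm(g, c(2, 3, 4, 1))                  # si p q r
  g <- array(t(C) %*% matrix(g, n, m^3), c(m, m, m, m))
  aperm(g, c(2, 3, 4, 1))                       # (pq|rs)
}

#' Fold frozen orbitals into an active-space Hamiltonian
#'
#' Builds the effective one-electron integrals and core constant of the
#' active window using the standard inactive-Fock expressions
#' `h_eff[pq] = h[pq] + sum_i (2 (pq|ii) - (pi|iq))` and
#' `e_core = E_nuc + sum_i 2 h[ii] + sum_ij (2 (ii|jj) - (ij|ji))`,
#' with `i`, `j` running over frozen occupied MOs.
#'
#' @param scf an `scf_reference`.
#' @param active an `active_space` consistent with `scf`.
#' @return An `active_hamiltonian` with `h_eff` (n_act x n_act), `g`
#'   (active two-electron tensor, chemists' convention), `e_core`,
#'   `n_active_electrons`, `n_active_orbitals`.
#' @export
fold_frozen_core <- function(scf, active) {
  if (length(intersect(active$active_mo_indices,
                       active$frozen_occupied_indices)) > 0) {
    stop("active and frozen orbital sets overlap")
  }
  C_all <- scf$mo_coefficients[, c(active$frozen_occupied_indices,
                                   active$active_mo_indices), drop = FALSE]
  nf <- length(active$frozen_occupied_indices)
  na <- active$n_active_orbitals
  h_mo <- .ao_to_mo_1e(scf$core_hamiltonian, C_all)
  g_mo <- .ao_to_mo_2e(scf$eri, C_all)

  fr <- seq_len(nf)
  ac <- nf + seq_len(na)
  e_core <- scf$e_nuc
  if (nf > 0) {
    e_core <- e_core + 2 * sum(diag(h_mo)[fr])
    for (i in fr) for (j in fr) {
      e_core <- e_core + 2 * g_mo[i, i, j, j] - g_mo[i, j, j, i]
    }
  }
  h_eff <- h_mo[ac, ac, drop = FALSE]
  if (nf > 0) {
    for (i in fr) {
      h_eff <- h_eff + 2 * g_mo[ac, ac, i, i] - g_mo[ac, i, i, ac]
    }
  }
  g_act <- g_mo[ac, ac, ac, ac, drop = FALSE]
  structure(list(h_eff = h_eff, g = g_act, e_core = e_core,
                 n_active_electrons = active$n_active_electrons,
                 n_active_orbitals = na),
            class = "active_hamiltonian")
}

#' @export
print.active_hamiltonian <- function(x, ...) {
  cat(sprintf("<active Hamiltonian: (%d,%d), e_core = %.10f Eh>\n",
              x$n_active_electrons, x$n_active_orbitals, x$e_core))
  invisible(x)
}

#' Hartree-Fock determinant energy of a folded Hamiltonian
#'
#' Evaluates the closed-shell determinant expectation value
#' `e_core + 2 sum_i h[ii] + sum_ij (2 (ii|jj) - (ij|ji))` over the
#' lowest `n_active_electrons / 2` active orbitals.  With a frontier window
#' this reproduces the parent SCF energy.
#'
#' @param ham an `active_hamiltonian`.
#' @export
hf_determinant_energy <- function(ham) {
  no <- ham$n_active_electrons %/% 2
  occ <- seq_len(no)
  e <- ham$e_core + 2 * sum(diag(ham$h_eff)[occ])
  for (i in occ) for (j in occ) {
    e <- e + 2 * ham$g[i, i, j, j] - ham$g[i, j, j, i]
  }
  e
}

#' Write / read an active-space Hamiltonian in FCIDUMP format
#'
#' Standard namelist header followed by 8-fold-symmetry-unique two-electron
#' records, one-electron records (`k = l = 0`) and the core constant
#' (`i = j = k = l = 0`).  Chemists' convention throughout.
#'
#' @param ham an `active_hamiltonian`.
#' @param path file path.
#' @export
write_fcidump <- function(ham, path) {
  n <- ham$n_active_orbitals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=0,", n,
                     ham$n_active_electrons), con)
  writeLines(sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16e %4d %4d %4d %4d", v, i, j, k, l)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ij <- (i - 1) * i / 2 + j
    for (k in seq_len(i)) for (l in seq_len(k)) {
      kl <- (k - 1) * k / 2 + l
      if (kl > ij) next
      v <- ham$g[i, j, k, l]
      if (abs(v) > 1e-16) writeLines(fmt(v, i, j, k, l), con)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    v <- ham$h_eff[i, j]
    if (abs(v) > 1e-16) writeLines(fmt(v, i, j, 0, 0), con)
  }
  writeLines(fmt(ham$e_core, 0, 0, 0, 0), con)
  invisible(path)
}

#' @rdname write_fcidump
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  hdr_end <- grep("^\\s*[/&]END", lines, ignore.case = TRUE)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP: no &END")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  n <- as.integer(sub(".*NORB\\s*=\\s*(\\d+).*", "\\1", hdr))
  nelec <- as.integer(sub(".*NELEC\\s*=\\s*(\\d+).*", "\\1", hdr))
  h <- matrix(0, n, n)
  g <- array(0, c(n, n, n, n))
  e_core <- 0
  for (line in lines[-seq_len(hdr_end)]) {
    if (!nzchar(trimws(line))) next
    p <- strsplit(trimws(line), "\\s+")[[1]]
    v <- as.numeric(p[1])
    ij <- as.integer(p[2:5])
    i <- ij[1]; j <- ij[2]; k <- ij[3]; l <- ij[4]
    if (i == 0) {
      e_core <- v
    } else if (k == 0) {
      h[i, j] <- v; h[j, i] <- v
    } else {
      for (idx in list(c(i,j,k,l), c(j,i,k,l), c(i,j,l,k), c(j,i,l,k),
                       c(k,l,i,j), c(l,k,i,j), c(k,l,j,i), c(l,k,j,i))) {
        g[idx[1], idx[2], idx[3], idx[4]] <- v
      }
    }
  }
  structure(list(h_eff = h, g = g, e_core = e_core,
                 n_active_electrons = nelec, n_active_orbitals = n),
            class = "active_hamiltonian")
}
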