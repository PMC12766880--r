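# Active-space selection: a frontier window of canonical MOs.

#' Select an active space of frontier molecular orbitals
#'
#' The window takes the `n_electrons / 2` highest occupied and the
#' `n_orbitals - n_electrons / 2` lowest virtual canonical MOs; the remaining
#' occupied MOs are frozen at double occupation.  Ties at the window edge are
#' broken by ascending orbital energy, then ascending index; a warning is
#' issued when the edge gap is below 1e-8 Hartree.  Explicit MO indices may be
#' supplied to override the frontier rule.
#'
#' @param scf an `scf_reference`.
#' @param n_electrons number of active electrons (even).
#' @param n_orbitals number of active spatial orbitals.
#' @param active_mo_indices optional explicit (1-based) MO indices.
#' @return An `active_space` with `n_active_electrons`, `n_active_orbitals`,
#'   `active_mo_indices`, `frozen_occupied_indices`, `n_qubits`.
#' @export
select_active_space <- function(scf, n_electrons, n_orbitals,
                                active_mo_indices = NULL) {
  if (n_electrons %% 2 != 0) stop("n_electrons must be even")
  n_mo <- length(scf$orbital_energies)
  nocc <- scf$n_occupied
  n_act_occ <- n_electrons %/% 2
  if (n_act_occ > nocc) stop("more active electrons than occupied orbitals")
  if (n_orbitals < n_act_occ) stop("active window smaller than its electrons")

  if (is.null(active_mo_indices)) {
    n_act_virt <- n_orbitals - n_act_occ
    if (nocc + n_act_virt > n_mo) stop("active window exceeds the MO list")
    active_mo_indices <- c(seq(nocc - n_act_occ + 1, nocc),
                           if (n_act_virt > 0) seq(nocc + 1, nocc + n_act_virt))
    eps <- scf$orbital_energies
    lo <- nocc - n_act_occ + 1
    hi <- nocc + n_act_virt
    if (lo > 1 && abs(eps[lo] - eps[lo - 1]) < 1e-8) {
      warning("near-degenerate orbitals at the lower active-window edge")
    }
    if (hi < n_mo && abs(eps[hi + 1] - eps[hi]) < 1e-8) {
      warning("near-degenerate orbitals at the upper active-window edge")
    }
  } else {
    active_mo_indices <- sort(as.integer(active_mo_indices))
    if (length(active_mo_indices) != n_orbitals) {
      stop("explicit active_mo_indices must have length n_orbitals")
    }
    if (any(active_mo_indices < 1 | active_mo_indices > n_mo)) {
      stop("active MO indices out of range")
    }
  }
  frozen <- setdiff(seq_len(nocc), active_mo_indices)
  if (2L * length(frozen) + n_electrons != scf$n_electrons) {
    stop("active/frozen bookkeeping does not reproduce the electron count")
  }
  structure(list(n_active_electrons = as.integer(n_electrons),
                 n_active_orbitals = as.integer(n_orbitals),
                 active_mo_indices = as.integer(active_mo_indices),
                 frozen_occupied_indices = as.integer(frozen),
                 n_qubits = 2L * as.integer(n_orbitals)),
            class = "active_space")
}

#' @export
print.active_space <- function(x, ...) {
  cat(sprintf("<active space (%d,%d): MOs [%s], %d frozen, %d qubits>\n",
              x$n_active_electrons, x$n_active_orbitals,
              paste(x$active_mo_indices, collapse = ","),
              length(x$frozen_occupied_indices), x$n_qubits))
  invisible(x)
}
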