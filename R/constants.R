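# Physical constants and element data.  Positions are Angstrom at the user
# surface and Bohr internally; energies are always Hartree.

#' Unit conversion constants
#'
#' `bohr_per_angstrom` converts Angstrom to Bohr (divide) and back (multiply);
#' `debye_per_au` converts a dipole moment from atomic units to Debye.
#'
#' @format Named numeric values.
#' @name units
NULL

#' @rdname units
#' @export
bohr_radius_angstrom <- 0.529177210903

#' @rdname units
#' @export
debye_per_au <- 2.541746473

.element_z <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L,
                O = 8L, F = 9L, Ne = 10L)

# Atomic masses (u), used only for center-of-mass bookkeeping.
.element_mass <- c(H = 1.00782503207, He = 4.002603, Li = 7.016004,
                   Be = 9.012182, B = 11.009305, C = 12.0, N = 14.003074,
                   O = 15.994915, F = 18.998403, Ne = 19.992440)

element_number <- function(symbol) {
  z <- .element_z[symbol]
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(symbol[is.na(z)], collapse = ", "))
  unname(z)
}

angstrom_to_bohr <- function(x) x / bohr_radius_angstrom
bohr_to_angstrom <- function(x) x * bohr_radius_angstrom
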