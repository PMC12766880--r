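# Molecular geometries: construction, XYZ I/O, and the packaged CH5+
# dissociation series.

#' Create a molecular geometry
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n_atoms x 3) of positions in Angstrom.
#' @param charge integer total molecular charge.
#' @param multiplicity integer spin multiplicity (2S + 1).
#' @param label optional text label.
#' @return An object of class `vqerdm_geometry` with fields `symbols`, `Z`,
#'   `coords` (Angstrom), `charge`, `multiplicity`, `label`.
#' @export
geometry <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                     label = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == length(symbols), all(is.finite(coords)))
  Z <- element_number(symbols)
  n_elec <- sum(Z) - charge
  if (n_elec <= 0) stop("electron count must be positive")
  structure(list(symbols = symbols, Z = Z, coords = coords,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity), label = label),
            class = "vqerdm_geometry")
}

#' @export
print.vqerdm_geometry <- function(x, ...) {
  cat(sprintf("<geometry '%s': %d atoms, charge %+d, multiplicity %d, %d electrons>\n",
              x$label, length(x$symbols), x$charge, x$multiplicity,
              n_electrons(x)))
  invisible(x)
}

#' Number of electrons in a geometry
#' @param geom a `vqerdm_geometry`.
#' @export
n_electrons <- function(geom) sum(geom$Z) - geom$charge

#' Nuclear repulsion energy (Hartree)
#' @param geom a `vqerdm_geometry`.
#' @export
nuclear_repulsion <- function(geom) {
  xyz <- angstrom_to_bohr(geom$coords)
  e <- 0
  n <- nrow(xyz)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    e <- e + geom$Z[i] * geom$Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  e
}

#' Read a geometry from an XYZ file
#'
#' Standard two-header-line dialect: atom count, comment, then
#' `symbol x y z` rows in Angstrom.  Charge and multiplicity are supplied by
#' the caller, not parsed from the comment line.
#'
#' @param path file path.
#' @param charge,multiplicity molecular charge and spin multiplicity.
#' @param label optional label; defaults to the comment line.
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L, label = NULL) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  comment <- if (length(lines) >= 2) trimws(lines[2]) else ""
  rows <- lines[seq(3, 2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  symbols <- vapply(parts, `[[`, "", 1)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  geometry(symbols, coords, charge, multiplicity,
           label = if (is.null(label)) comment else label)
}

#' Write a geometry to an XYZ file
#' @param geom a `vqerdm_geometry`.
#' @param path file path.
#' @param comment comment line content.
#' @export
write_xyz <- function(geom, path, comment = geom$label) {
  lines <- c(sprintf("%d", length(geom$symbols)), comment,
             sprintf("%-2s %18.12f %18.12f %18.12f", geom$symbols,
                     geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged CH5+ dissociation geometries
#'
#' Returns the packaged protonated-methane geometry at dissociation coordinate
#' `R`, defined as the distance between the carbon and the center of mass of
#' the leaving H2 pair (atoms H3, H4).  Available values are 1.3 (equilibrium
#' region), 1.4, 1.6, 1.8 and 2.1 Angstrom.
#'
#' The packaged structures are synthetic stand-ins: Cs-symmetric geometries
#' optimized in-package at the CASCI(4,4)/STO-3G level with the C-(H2 c.o.m.)
#' distance constrained to `R` (see the package vignette for provenance).
#'
#' @param R dissociation coordinate in Angstrom; one of 1.3, 1.4, 1.6, 1.8, 2.1.
#' @return A `vqerdm_geometry` with charge +1 and multiplicity 1.
#' @export
ch5_geometry <- function(R) {
  avail <- c(1.3, 1.4, 1.6, 1.8, 2.1)
  i <- which(abs(avail - R) < 1e-9)
  if (length(i) != 1) {
    stop(sprintf("no packaged CH5+ geometry at R = %s; available: %s",
                 format(R), paste(format(avail), collapse = ", ")))
  }
  path <- system.file("extdata",
                      sprintf("ch5_R%.1f_synthetic.xyz", avail[i]),
                      package = "vqerdm", mustWork = TRUE)
  read_xyz(path, charge = 1L, multiplicity = 1L,
           label = sprintf("CH5+ R=%.1f (synthetic)", avail[i]))
}

#' Distance from carbon to the center of mass of the leaving H2 pair
#'
#' Validation utility for the CH5+ fixtures: recomputes the dissociation
#' coordinate from the coordinates.  The leaving pair is H3/H4 (atom indices
#' 3 and 4 in the packaged ordering C1, H2 ... H6).
#'
#' @param geom a CH5+ `vqerdm_geometry`.
#' @param carbon index of the carbon atom.
#' @param pair indices of the two leaving hydrogens.
#' @return distance in Angstrom.
#' @export
ch5_dissociation_coordinate <- function(geom, carbon = 1L, pair = c(3L, 4L)) {
  m <- .element_mass[geom$symbols[pair]]
  com <- colSums(geom$coords[pair, , drop = FALSE] * m) / sum(m)
  sqrt(sum((geom$coords[carbon, ] - com)^2))
}
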