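# STO-3G basis construction.  Exponents/coefficients are the standard
# published STO-3G parameters; coefficients are stored for normalized
# primitives and each contracted shell is renormalized to unit self-overlap.

.sto3g <- list(
  H = list(
    list(l = 0L,
         exponents = c(3.42525091, 0.62391373, 0.16885540),
         coefficients = c(0.15432897, 0.53532814, 0.44463454))
  ),
  C = list(
    list(l = 0L,
         exponents = c(71.6168370, 13.0450960, 3.5305122),
         coefficients = c(0.15432897, 0.53532814, 0.44463454)),
    list(l = 0L,
         exponents = c(2.9412494, 0.6834831, 0.2222899),
         coefficients = c(-0.09996723, 0.39951283, 0.70011547)),
    list(l = 1L,
         exponents = c(2.9412494, 0.6834831, 0.2222899),
         coefficients = c(0.15591627, 0.60768372, 0.39195739))
  )
)

.double_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# Normalization of a primitive Cartesian Gaussian x^l exp(-a r^2) (axial
# component; all components of an s or p shell share this value).
.primitive_norm <- function(a, l) {
  (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.double_factorial(2 * l - 1))
}

#' Build the shell list for a geometry
#'
#' Returns the list of contracted Gaussian shells consumed by the integral
#' engine.  Each shell carries `l`, `center` (Bohr), `exponents`,
#' `coefficients` (normalized), the owning `atom` index and an `ao_labels`
#' vector.  Only the minimal STO-3G basis is packaged; shells with l <= 1 are
#' renormalized per shell (valid because s and p components share their
#' primitive normalization).
#'
#' @param geom a `vqerdm_geometry`.
#' @param basis basis set name; only `"sto-3g"` is available.
#' @return list with `shells`, `nao`, `ao_atom` (AO -> atom index) and
#'   `ao_labels`.
#' @export
build_basis <- function(geom, basis = "sto-3g") {
  if (tolower(basis) != "sto-3g") {
    stop("only the STO-3G basis is packaged; requested: ", basis)
  }
  shells <- list()
  ao_atom <- integer(0)
  ao_labels <- character(0)
  shell_names <- list(H = c("1s"), C = c("1s", "2s", "2p"))
  for (ia in seq_along(geom$symbols)) {
    sym <- geom$symbols[ia]
    if (is.null(.sto3g[[sym]])) {
      stop("no packaged STO-3G shells for element ", sym)
    }
    for (k in seq_along(.sto3g[[sym]])) {
      tpl <- .sto3g[[sym]][[k]]
      norms <- vapply(tpl$exponents, .primitive_norm, numeric(1), l = tpl$l)
      coefs <- tpl$coefficients * norms
      # contracted self-overlap (axial component)
      p_sum <- outer(tpl$exponents, tpl$exponents, `+`)
      s_self <- sum(outer(coefs, coefs) * (pi / p_sum)^1.5 *
                    .double_factorial(2 * tpl$l - 1) / (2 * p_sum)^tpl$l)
      coefs <- coefs / sqrt(s_self)
      shells[[length(shells) + 1]] <- list(
        l = tpl$l, center = angstrom_to_bohr(geom$coords[ia, ]),
        exponents = tpl$exponents, coefficients = coefs, atom = ia)
      ncomp <- (tpl$l + 1) * (tpl$l + 2) / 2
      ao_atom <- c(ao_atom, rep(ia, ncomp))
      base <- shell_names[[sym]][k]
      labs <- if (tpl$l == 0) base else paste0(base, c("x", "y", "z"))
      ao_labels <- c(ao_labels, paste0(sym, ia, " ", labs))
    }
  }
  list(shells = shells, nao = length(ao_atom), ao_atom = ao_atom,
       ao_labels = ao_labels)
}
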