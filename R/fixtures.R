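# Deterministic toy-system fixtures so every module is testable without any
# download: H2, H3+, a linear H4 chain and the packaged CH5+ series.

#' Built-in fixture systems
#'
#' * `h2`: H2 at 0.735 Angstrom (2 electrons, 2 AOs; (2,2) is the full space).
#' * `h3plus`: equilateral H3+ with 0.90 Angstrom sides (2 electrons, 3 AOs).
#' * `h4_chain`: linear H4, 1.0 Angstrom spacing (4 electrons; CASCI(4,4) = FCI).
#' * `ch5_1.3` ... `ch5_2.1`: the packaged CH5+ dissociation geometries.
#'
#' @param name fixture name.
#' @param with_scf also run and attach the RHF reference.
#' @return list with `geometry` and (optionally) `scf`.
#' @export
make_fixture <- function(name, with_scf = FALSE) {
  geom <- switch(name,
    h2 = geometry(c("H", "H"),
                  rbind(c(0, 0, 0), c(0, 0, 0.735)), 0L, 1L, label = "H2"),
    h3plus = {
      a <- 0.90
      geometry(c("H", "H", "H"),
               rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0)),
               1L, 1L, label = "H3+")
    },
    h4_chain = geometry(rep("H", 4),
                        cbind(0, 0, seq(0, 3)), 0L, 1L, label = "H4 chain"),
    {
      if (grepl("^ch5_", name)) {
        ch5_geometry(as.numeric(sub("^ch5_", "", name)))
      } else {
        stop("unknown fixture: ", name,
             " (available: h2, h3plus, h4_chain, ch5_<R>)")
      }
    })
  out <- list(geometry = geom)
  if (with_scf) out$scf <- run_scf(geom)
  out
}
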