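# 1-RDM measurement, spin summation, embedding.

test_that("HF state measures to the HF occupation matrix", {
  v <- hf_reference_state(4L, 2L)       # |1100>
  D <- measure_active_rdm(v)
  expect_equal(unname(Re(diag(D))), c(1, 1, 0, 0), tolerance = 1e-12)
  expect_lt(max(Mod(D - diag(diag(D)))), 1e-12)
})

test_that("measured RDM equals dense ladder-matrix oracle on random states", {
  for (case_ in list(c(4, 2, 1), c(6, 3, 2), c(8, 4, 3))) {
    n <- case_[1]
    psi <- random_sector_state(n, case_[2], seed = case_[3])
    D <- measure_active_rdm(psi)
    for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
      A <- as.matrix(ladder_operator_matrix(c(p, q), c(TRUE, FALSE), n))
      expect_equal(D[p + 1, q + 1], sum(Conj(psi) * (A %*% psi)),
                   tolerance = 1e-10)
    }
    # invariants: Hermitian, occupations in [0,1], eigenvalues in [0,1]
    expect_lt(max(Mod(D - Conj(t(D)))), 1e-12)
    expect_true(all(Re(diag(D)) >= -1e-9 & Re(diag(D)) <= 1 + 1e-9))
    ev <- eigen(D, only.values = TRUE)$values
    expect_true(all(Re(ev) > -1e-9 & Re(ev) < 1 + 1e-9))
  }
})

test_that("measurement rejects unnormalized states", {
  expect_error(measure_active_rdm(c(1, 1, 0, 0) + 0i), "normalized")
})

test_that("CASCI ground state loaded as a statevector reproduces the CI 1-RDM", {
  for (name in c("h2", "h4_chain")) {
    ci <- fixture_casci(name, 2, 2)
    psi <- ci_statevector(ci)
    expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-12)
    D <- spin_sum(measure_active_rdm(psi))
    expect_equal(D, ci$one_rdm, tolerance = 1e-10)
  }
})

test_that("spin_sum contracts spins, preserves trace, ignores cross blocks", {
  D <- diag(c(1, 1, 0, 0)) + 0i
  expect_equal(spin_sum(D), diag(c(2, 0)), tolerance = 1e-14)

  # real-amplitude state: the spin-summed spatial RDM is real-representable
  psi <- random_sector_state(4, 2, seed = 4, complex_amp = FALSE)
  Dm <- measure_active_rdm(psi)
  expect_equal(sum(diag(spin_sum(Dm))), Re(sum(diag(Dm))), tolerance = 1e-12)
  # alpha-beta cross blocks are never read
  Dm2 <- Dm
  Dm2[1, 2] <- 99; Dm2[2, 1] <- 99; Dm2[3, 4] <- -7; Dm2[4, 3] <- -7
  expect_equal(spin_sum(Dm2), spin_sum(Dm), tolerance = 1e-14)

  Dbad <- Dm; Dbad[1, 1] <- Dbad[1, 1] + 1e-4i; Dbad[3, 3] <- Dbad[3, 3] - 1e-4i
  expect_error(spin_sum(Dbad), "imaginary residue")
})

test_that("embedding the HF active block reproduces the HF AO density", {
  sys <- fixture_system("h4_chain", 2, 2)
  d_hf <- diag(c(2, 0))                  # active window holds HOMO + LUMO
  gamma <- embed_active_rdm(d_hf, sys$scf, sys$active)
  expect_lt(max(abs(gamma - sys$scf$hf_density_ao)), 1e-10)
  # idempotent under repetition and trace-conserving for any input
  set.seed(6)
  d_any <- crossprod(matrix(rnorm(4), 2)) / 4
  d_any <- d_any * (2 / sum(diag(d_any)))
  g2 <- embed_active_rdm(d_any, sys$scf, sys$active)
  expect_equal(sum(g2 * sys$scf$overlap), sys$scf$n_electrons,
               tolerance = 1e-8)
})

test_that("natural occupations from optimization runs stay within [0, 2]", {
  sys <- fixture_system("h4_chain", 2, 2)
  res <- run_vqe("vqe_ld", build_kupccgsd(sys$active, 1), sys$qubit_ham,
                 convergence_settings())
  ev <- eigen(res$final_spatial_rdm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9 & ev < 2 + 1e-9))
  expect_equal(sum(diag(res$final_spatial_rdm)), 2, tolerance = 1e-8)
})
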