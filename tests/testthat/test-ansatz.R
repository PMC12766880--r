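# Ansatz circuits: construction, state preparation, symmetries, gradients.

test_that("Hartree-Fock reference state occupies the lowest spin orbitals", {
  sys22 <- fixture_system("h2", 2, 2)
  v <- hf_reference_state(sys22$active)
  expect_equal(which(Mod(v) > 0), strtoi("1100", base = 2) + 1)   # |1100>
  v8 <- hf_reference_state(8L, 4L)
  expect_equal(which(Mod(v8) > 0), strtoi("11110000", base = 2) + 1)  # |11110000>
  expect_error(hf_reference_state(2L, 3L), "more electrons")
})

test_that("HF-state energy equals the folded-integral determinant energy", {
  sys <- fixture_system("h4_chain", 2, 2)
  v <- hf_reference_state(sys$active)
  e <- pauli_expectation(v, sys$qubit_ham)
  expect_equal(e, hf_determinant_energy(sys$ham), tolerance = 1e-10)
})

test_that("k-UpCCGSD parameter counts follow the excitation enumeration", {
  sys22 <- fixture_system("h2", 2, 2)
  c1 <- build_kupccgsd(sys22$active, 1)
  expect_equal(c1$parameter_count, 3L)          # 2 singles + 1 paired double
  c3 <- build_kupccgsd(sys22$active, 3)
  expect_equal(c3$parameter_count, 9L)
  sys44 <- fixture_system("h4_chain", 4, 4)
  expect_equal(build_kupccgsd(sys44$active, 1)$parameter_count,
               2L * choose(4, 2) + choose(4, 2))  # 12 singles + 6 doubles
})

test_that("GateFabric tiling: counts, identity at zero, brick offsets", {
  act22 <- fixture_system("h2", 2, 2)$active
  g1 <- build_gatefabric(act22, 1)
  expect_equal(g1$parameter_count, 2L)          # exactly 1 tile
  expect_equal(length(g1$excitation_list), 1L)
  expect_equal(prepare_state(g1, c(0, 0)), hf_reference_state(act22))

  act44 <- fixture_system("h4_chain", 4, 4)$active
  g2 <- build_gatefabric(act44, 2)
  # layer 1: tiles at spatial (1,2) and (3,4); layer 2: one brick at (2,3)
  expect_equal(length(g2$excitation_list), 3L)
  expect_equal(g2$parameter_count, 6L)
  expect_error(build_gatefabric(structure(list(n_qubits = 2L),
                                          class = "active_space"), 1),
               "even number")
})

test_that("prepared states are normalized and reduce to HF at theta = 0", {
  for (build in list(function(a) build_kupccgsd(a, 1),
                     function(a) build_gatefabric(a, 2))) {
    act <- fixture_system("h4_chain", 2, 2)$active
    circ <- build(act)
    expect_equal(prepare_state(circ, numeric(circ$parameter_count)),
                 hf_reference_state(act))
    set.seed(8)
    for (rep in 1:5) {
      th <- rnorm(circ$parameter_count)
      v <- prepare_state(circ, th)
      expect_equal(sum(Mod(v)^2), 1, tolerance = 1e-12)
    }
    expect_error(prepare_state(circ, numeric(circ$parameter_count + 1)),
                 "length")
  }
})

test_that("both ansaetze conserve particle number exactly", {
  sys <- fixture_system("h4_chain", 4, 4)
  Nm <- number_operator_matrix(8)
  N2 <- Nm %*% Nm
  set.seed(9)
  for (circ in list(build_kupccgsd(sys$active, 1),
                    build_gatefabric(sys$active, 2))) {
    th <- rnorm(circ$parameter_count)
    v <- prepare_state(circ, th)
    nv <- dense_expect(v, Nm)
    expect_equal(nv, 4, tolerance = 1e-10)
    # variance is zero up to cancellation noise in <N^2> - <N>^2 (~16 * eps)
    expect_lt(abs(dense_expect(v, N2) - nv^2), 1e-12)
  }
})

test_that("excitation generators satisfy the Givens identity G^3 = -G", {
  circ <- build_kupccgsd(fixture_system("h4_chain", 2, 2)$active, 1)
  for (g in circ$gates) {
    G3 <- g$G %*% g$G2
    expect_lt(max(abs(G3 + g$G)), 1e-12)
  }
})

test_that("adjoint gradients match central finite differences", {
  sys <- fixture_system("h4_chain", 2, 2)
  set.seed(10)
  for (circ in list(build_kupccgsd(sys$active, 1),
                    build_kupccgsd(sys$active, 2),
                    build_gatefabric(sys$active, 1),
                    build_gatefabric(sys$active, 3))) {
    Hm <- Re(pauli_to_matrix(sys$qubit_ham))
    for (rep in 1:5) {
      th <- rnorm(circ$parameter_count, 0, 0.5)
      g_ad <- energy_and_gradient(circ, th, Hm)$gradient
      g_fd <- fd_gradient(function(t_)
        energy_and_gradient(circ, t_, Hm)$energy, th)
      expect_lt(max(abs(g_ad - g_fd)), 1e-6)
    }
  }
})

test_that("gradient vanishes at a tight variational minimum", {
  sys <- fixture_system("h2", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  res <- run_vqe("vqe", circ, sys$qubit_ham,
                 convergence_settings(e_tol = 1e-13, max_iterations = 20000))
  g <- energy_and_gradient(circ, res$final_theta, sys$qubit_ham)$gradient
  expect_lt(sqrt(sum(g^2)), 1e-5)
})

test_that("minimized k-UpCCGSD energy reaches CASCI on the same Hamiltonian", {
  sys <- fixture_system("h2", 2, 2)
  ci <- fixture_casci("h2", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  res <- run_vqe("vqe", circ, sys$qubit_ham,
                 convergence_settings(e_tol = 1e-12, max_iterations = 20000))
  expect_equal(res$final_energy, ci$energy, tolerance = 1e-8)
  expect_gt(res$final_energy, ci$energy - 1e-9)   # variational bound
})

test_that("circuit JSON export lists every gate with its parameter index", {
  circ <- build_kupccgsd(fixture_system("h2", 2, 2)$active, 1)
  js <- jsonlite::fromJSON(circuit_to_json(circ))
  expect_equal(js$parameter_count, 3)
  expect_equal(nrow(js$gates), length(circ$gates))
  expect_true(all(js$gates$param_index <= circ$parameter_count))
})
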