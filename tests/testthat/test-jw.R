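# Jordan-Wigner mapping and Pauli-operator algebra.

test_that("single-orbital number Hamiltonian maps to eps/2 (I - Z)", {
  ham <- structure(list(h_eff = matrix(0.37), g = array(0, c(1, 1, 1, 1)),
                        e_core = 0, n_active_electrons = 0L,
                        n_active_orbitals = 1L), class = "active_hamiltonian")
  # one spatial orbital -> two spin orbitals; each contributes eps/2 (I - Z)
  H <- jordan_wigner_hamiltonian(ham)
  expect_equal(sort(names(H$terms)), c("II", "IZ", "ZI"))
  expect_equal(Re(H$terms[["II"]]), 0.37, tolerance = 1e-12)
  expect_equal(Re(H$terms[["ZI"]]), -0.185, tolerance = 1e-12)
  expect_equal(Re(H$terms[["IZ"]]), -0.185, tolerance = 1e-12)
})

test_that("JW ladder operators satisfy the anticommutation relations", {
  n <- 3
  for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
    ap <- pauli_to_matrix(jw_ladder_product(p, FALSE, n))
    aqd <- pauli_to_matrix(jw_ladder_product(q, TRUE, n))
    anti <- ap %*% aqd + aqd %*% ap
    target <- if (p == q) diag(2^n) else matrix(0, 2^n, 2^n)
    expect_lt(max(Mod(anti - target)), 1e-12)
  }
})

test_that("JW Hamiltonian coefficients are real and the matrix is Hermitian", {
  H <- fixture_system("h2", 2, 2)$qubit_ham
  expect_lt(max(abs(Im(H$terms))), 1e-12)
  Hm <- pauli_to_matrix(H)
  expect_lt(max(Mod(Hm - Conj(t(Hm)))), 1e-12)
})

test_that("JW Hamiltonian ground energy equals the CI energy (dense oracle)", {
  sys <- fixture_system("h2", 2, 2)
  ci <- fixture_casci("h2", 2, 2)
  Hm <- pauli_to_matrix(sys$qubit_ham)
  expect_equal(min(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values),
               ci$energy, tolerance = 1e-10)
})

test_that("particle number commutes with the mapped Hamiltonian", {
  sys <- fixture_system("h4_chain", 2, 2)
  Hm <- Re(pauli_to_matrix(sys$qubit_ham))
  Nm <- as.matrix(number_operator_matrix(4))
  expect_lt(max(abs(Hm %*% Nm - Nm %*% Hm)), 1e-10)
})

test_that("jw_excitation_operator matches the printed Hermitian combinations", {
  ops <- jw_excitation_operator(0, 0, 2)
  expect_equal(Re(ops$re$terms[["II"]]), 0.5, tolerance = 1e-14)
  expect_equal(Re(ops$re$terms[["ZI"]]), -0.5, tolerance = 1e-14)
  v0 <- c(1, 0, 0, 0) + 0i             # |00>
  v1 <- c(0, 0, 1, 0) + 0i             # |10>: qubit 0 occupied
  expect_equal(pauli_expectation(v0, ops$re), 0, tolerance = 1e-14)
  expect_equal(pauli_expectation(v1, ops$re), 1, tolerance = 1e-14)

  ops01 <- jw_excitation_operator(0, 1, 2)
  expect_equal(Re(ops01$re$terms[["XX"]]), 0.25, tolerance = 1e-14)
  expect_equal(Re(ops01$re$terms[["YY"]]), 0.25, tolerance = 1e-14)
  expect_equal(sort(names(ops01$im$terms)), c("XY", "YX"))

  expect_error(jw_excitation_operator(2, 1, 4), "p <= q")
})

test_that("excitation-operator expectations equal dense ladder matrices", {
  n <- 3
  psi <- random_sector_state(n, 2, seed = 42)
  for (p in 0:(n - 1)) for (q in p:(n - 1)) {
    ops <- jw_excitation_operator(p, q, n)
    A <- as.matrix(ladder_operator_matrix(c(p, q), c(TRUE, FALSE), n))
    ref <- sum(Conj(psi) * (A %*% psi))
    expect_equal(pauli_expectation(psi, ops$re), Re(ref), tolerance = 1e-12)
    if (p < q) {
      expect_equal(pauli_expectation(psi, ops$im), Im(ref), tolerance = 1e-12)
    }
  }
})

test_that("pauli_expectation reproduces elementary and dense-oracle values", {
  v00 <- c(1, 0, 0, 0) + 0i
  zz <- pauli_op(2, c(ZZ = 1))
  expect_equal(pauli_expectation(v00, zz), 1)
  plus <- c(1, 1) / sqrt(2) + 0i
  expect_equal(pauli_expectation(plus, pauli_op(1, c(X = 1))), 1)

  set.seed(5)
  n <- 4
  psi <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  words <- apply(matrix(sample(c("I", "X", "Y", "Z"), 12 * n, TRUE), 12), 1,
                 paste, collapse = "")
  words <- unique(words)
  op <- pauli_op(n, setNames(rnorm(length(words)), words))
  Hm <- pauli_to_matrix(op)
  ref <- Re(sum(Conj(psi) * (Hm %*% psi)))
  expect_equal(pauli_expectation(psi, op, imag_tol = Inf), ref,
               tolerance = 1e-12)
})

test_that("pauli algebra: multiplication and identity bookkeeping", {
  x <- pauli_op(1, c(X = 1))
  y <- pauli_op(1, c(Y = 1))
  xy <- pauli_multiply(x, y)
  expect_equal(xy$terms[["Z"]], complex(real = 0, imaginary = 1))
  # X * X = I
  expect_equal(names(pauli_multiply(x, x)$terms), "I")
})
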