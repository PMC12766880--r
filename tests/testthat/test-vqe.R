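# The optimizer loops: DeltaD, w_D, the augmented loss, and the three
# convergence behaviours.

test_that("delta_d is the RMSD over all N^2 entries", {
  A <- matrix(rnorm(16), 4)
  expect_equal(delta_d(A, A), 0)
  expect_equal(delta_d(A + 0.37, A), 0.37, tolerance = 1e-14)
  set.seed(12)
  B <- A + matrix(rnorm(16, 0, 0.1), 4)
  acc <- 0
  for (p in 1:4) for (q in 1:4) acc <- acc + (A[p, q] - B[p, q])^2
  expect_equal(delta_d(A, B), sqrt(acc / 16), tolerance = 1e-14)
  expect_error(delta_d(A, matrix(0, 3, 3)), "shape")
})

test_that("weight_wd follows the gradient-norm ratio with its zero rules", {
  expect_equal(weight_wd(c(2, 0), c(0, 4), 0.05), 0.025)
  expect_equal(weight_wd(c(1, 1), c(0, 0), 0.5), 0)
  expect_equal(weight_wd(c(1, 1), c(1, 2), 0), 0)
})

test_that("loss gradient matches finite differences away from DeltaD = 0", {
  sys <- fixture_system("h4_chain", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  ctx <- vqe_context(circ, sys$qubit_ham)
  set.seed(13)
  d_prev <- diag(c(1.9, 0.1))
  for (rep in 1:5) {
    th <- rnorm(circ$parameter_count, 0, 0.4)
    lg <- loss_and_gradient(circ, th, sys$qubit_ham, d_prev, f = 0.3,
                            context = ctx)
    expect_gt(lg$delta_d, 1e-4)
    w_d <- lg$w_d   # frozen weight, as in the analytic gradient definition
    fd <- fd_gradient(function(t_) {
      l2 <- loss_and_gradient(circ, t_, sys$qubit_ham, d_prev, f = 0.3,
                              context = ctx)
      l2$energy + w_d * l2$delta_d
    }, th, h = 1e-6)
    expect_lt(max(abs(lg$gradient - fd)), 1e-6)
  }
})

test_that("w_D = 0 collapses the loss onto the plain energy bitwise", {
  sys <- fixture_system("h2", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  th <- c(0.1, -0.2, 0.3)
  lg <- loss_and_gradient(circ, th, sys$qubit_ham,
                          d_prev = diag(c(2, 0)), f = 0)
  eg <- energy_and_gradient(circ, th, sys$qubit_ham)
  expect_identical(lg$loss, eg$energy)
  expect_identical(lg$gradient, eg$gradient)
})

test_that("theta at the previous RDM gives DeltaD = 0 and a zero subgradient", {
  sys <- fixture_system("h2", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  th <- c(0.05, 0.02, -0.1)
  state <- prepare_state(circ, th)
  d_here <- spin_sum(measure_active_rdm(state))
  lg <- loss_and_gradient(circ, th, sys$qubit_ham, d_prev = d_here, f = 0.3)
  expect_equal(lg$delta_d, 0)
  expect_equal(lg$grad_d, numeric(3))
  expect_identical(lg$loss, lg$energy)
})

test_that("zero-initialized first iteration starts at the HF energy", {
  sys <- fixture_system("h4_chain", 2, 2)
  for (v in c("vqe", "vqe_star", "vqe_ld")) {
    res <- run_vqe(v, build_kupccgsd(sys$active, 1), sys$qubit_ham,
                   convergence_settings(max_iterations = 3L))
    expect_equal(res$trajectory$energy[1], sys$scf$hf_energy,
                 tolerance = 1e-10)
  }
})

test_that("all three variants converge H2 to CASCI within e_tol scale", {
  sys <- fixture_system("h2", 2, 2)
  ci <- fixture_casci("h2", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  for (v in c("vqe", "vqe_star", "vqe_ld")) {
    res <- run_vqe(v, circ, sys$qubit_ham, convergence_settings())
    expect_true(res$converged)
    expect_lt(abs(res$final_energy - ci$energy), 1e-6)
    if (v != "vqe") {
      expect_lt(tail(res$trajectory$delta_d, 1), 1e-6)  # by construction
    }
  }
})

test_that("plain-VQE energy trajectory is non-increasing for small steps", {
  sys <- fixture_system("h4_chain", 2, 2)
  res <- run_vqe("vqe", build_kupccgsd(sys$active, 1), sys$qubit_ham,
                 convergence_settings(learning_rate = 0.1, e_tol = 1e-9))
  expect_true(all(diff(res$trajectory$energy) < 1e-9))
})

test_that("VQE-LD with f = 0 reproduces the plain-VQE trajectory bitwise", {
  sys <- fixture_system("h4_chain", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  r_vqe <- run_vqe("vqe", circ, sys$qubit_ham,
                   convergence_settings(max_iterations = 40L, e_tol = 1e-14))
  r_ld0 <- run_vqe("vqe_ld", circ, sys$qubit_ham,
                   convergence_settings(max_iterations = 40L, e_tol = 1e-14,
                                        f = 0))
  n <- min(nrow(r_vqe$trajectory), nrow(r_ld0$trajectory))
  expect_identical(r_vqe$trajectory$energy[1:n], r_ld0$trajectory$energy[1:n])
  expect_identical(r_vqe$theta_snapshots[[n]], r_ld0$theta_snapshots[[n]])
})

test_that("two identical runs are bitwise identical (determinism)", {
  sys <- fixture_system("h4_chain", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  r1 <- run_vqe("vqe_ld", circ, sys$qubit_ham, convergence_settings())
  r2 <- run_vqe("vqe_ld", circ, sys$qubit_ham, convergence_settings())
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_theta, r2$final_theta)
})

test_that("max_iterations flags non-convergence instead of raising", {
  sys <- fixture_system("h2", 2, 2)
  res <- run_vqe("vqe", build_kupccgsd(sys$active, 1), sys$qubit_ham,
                 convergence_settings(max_iterations = 3L, e_tol = 1e-14))
  expect_false(res$converged)
  expect_equal(res$steps, 3)
})

test_that("spin-orbital DeltaD basis is a bounded rescaling of the spatial one", {
  sys <- fixture_system("h4_chain", 2, 2)
  circ <- build_kupccgsd(sys$active, 1)
  r_sp <- run_vqe("vqe_star", circ, sys$qubit_ham,
                  convergence_settings(max_iterations = 30L, e_tol = 1e-14))
  r_so <- run_vqe("vqe_star", circ, sys$qubit_ham,
                  convergence_settings(max_iterations = 30L, e_tol = 1e-14,
                                       delta_d_basis = "spin"))
  # identical parameter trajectories (updates don't involve DeltaD for vqe_star)
  expect_identical(r_sp$trajectory$energy, r_so$trajectory$energy)
  ratio <- r_so$trajectory$delta_d[-1] / r_sp$trajectory$delta_d[-1]
  expect_true(all(ratio > 0.2 & ratio < 1.01))
})
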