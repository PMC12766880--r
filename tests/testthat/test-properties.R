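# 1-RDM-derived properties: density, ESP, dipole, Mulliken, critical points,
# cube files.

# single normalized primitive s-Gaussian as a minimal basis
.single_gaussian_basis <- function(alpha = 1.3) {
  N <- (2 * alpha / pi)^0.75
  list(shells = list(list(l = 0L, center = c(0, 0, 0), exponents = alpha,
                          coefficients = N, atom = 1L)),
       nao = 1L, ao_atom = 1L, ao_labels = "H1 1s")
}

test_that("density of one normalized s-Gaussian matches the closed form", {
  alpha <- 1.3
  bs <- .single_gaussian_basis(alpha)
  out <- density_at(matrix(1), bs, rbind(c(0, 0, 0), c(0.3, -0.2, 0.5)),
                    deriv = 0L)
  expect_equal(out$rho[1], (2 * alpha / pi)^1.5, tolerance = 1e-12)
  r2 <- sum(c(0.3, -0.2, 0.5)^2)
  expect_equal(out$rho[2], (2 * alpha / pi)^1.5 * exp(-2 * alpha * r2),
               tolerance = 1e-12)
})

test_that("grid integral of the density converges to N_elec", {
  scf <- fixture_system("h2", 2, 2)$scf
  box_integral <- function(res, pad) {
    grid <- default_grid(scf$geometry, resolution = res, padding = pad)
    f <- density_field(scf$hf_density_ao, scf$basis, grid)
    sum(f$values) * abs(det(grid$axes))
  }
  # within 1% at every cube resolution used in practice
  errs_res <- vapply(c(0.2, 0.1, 0.05), function(r)
    abs(box_integral(r, 4) - 2), numeric(1))
  expect_true(all(errs_res / 2 < 0.01))
  # the residual is box truncation: it decays monotonically (and fast) with
  # padding, while the lattice sum itself is already converged at 0.2 Bohr
  errs_pad <- vapply(c(4, 6, 8), function(p)
    abs(box_integral(0.2, p) - 2), numeric(1))
  expect_true(all(diff(errs_pad) < 0))
  expect_lt(errs_pad[3], 1e-9)
})

test_that("analytic density gradient and Hessian match finite differences", {
  # carbon-containing system exercises the p-shell derivative code
  g <- geometry(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  bs <- build_basis(g)
  set.seed(14)
  gamma <- crossprod(matrix(rnorm(36), 6))
  pts <- matrix(rnorm(240, sd = 1.2), ncol = 3)
  # keep sampling away from the nuclear cusp region, where the finite
  # difference itself is the limiting approximation
  xyz <- g$coords / bohr_radius_angstrom
  dmin <- pmin(sqrt(colSums((t(pts) - xyz[1, ])^2)),
               sqrt(colSums((t(pts) - xyz[2, ])^2)))
  pts <- pts[dmin > 0.6, , drop = FALSE][1:50, ]
  ev <- density_at(gamma, bs, pts, deriv = 2L)
  h <- 1e-5
  for (k in 1:3) {
    dp <- pts; dp[, k] <- dp[, k] + h
    dm <- pts; dm[, k] <- dm[, k] - h
    g_fd <- (density_at(gamma, bs, dp)$rho - density_at(gamma, bs, dm)$rho) /
      (2 * h)
    expect_lt(max(abs(ev$grad[, k] - g_fd) / pmax(1, abs(g_fd))), 1e-7)
    gp <- density_at(gamma, bs, dp, deriv = 1L)$grad
    gm <- density_at(gamma, bs, dm, deriv = 1L)$grad
    for (l in 1:3) {
      h_fd <- (gp[, l] - gm[, l]) / (2 * h)
      expect_lt(max(abs(ev$hessian[, k, l] - h_fd) / pmax(1, abs(h_fd))), 1e-6)
    }
  }
})

test_that("ESP: bare nucleus, monopole far field, quadrature oracle", {
  g <- make_fixture("h2")$geometry
  bs <- build_basis(g)
  # gamma = 0: pure nuclear potential
  pt <- rbind(c(0, 0, -2.0))
  v <- esp_at(matrix(0, 2, 2), g, bs, pt)
  xyz <- g$coords / bohr_radius_angstrom
  expect_equal(v, 1 / 2 + 1 / sqrt(sum((xyz[2, ] - c(0, 0, -2))^2)),
               tolerance = 1e-12)

  # far field of a +1 ion approaches q / (distance from the charge centroid)
  h3 <- make_fixture("h3plus", with_scf = TRUE)
  centroid <- colMeans(h3$geometry$coords / bohr_radius_angstrom)
  pt_far <- rbind(centroid + c(50, 0, 0))
  vfar <- esp_at(h3$scf$hf_density_ao, h3$geometry, h3$scf$basis, pt_far)
  expect_equal(vfar * 50, 1, tolerance = 0.01)

  # electronic term vs numerical quadrature of -int rho / |r - r'|
  scf <- fixture_system("h2", 2, 2)$scf
  grid <- default_grid(scf$geometry, resolution = 0.08, padding = 5)
  pts_g <- grid_points(grid)
  rho <- density_at(scf$hf_density_ao, scf$basis, pts_g)$rho
  vox <- abs(det(grid$axes))
  test_pts <- rbind(c(4, 0, 0.7), c(0, -3.5, 2))
  v_full <- esp_at(scf$hf_density_ao, scf$geometry, scf$basis, test_pts)
  for (i in 1:2) {
    r <- sqrt(colSums((t(pts_g) - test_pts[i, ])^2))
    v_elec_quad <- -sum(rho / r) * vox
    v_nuc <- sum(scf$geometry$Z /
                   sqrt(colSums((t(scf$geometry$coords / bohr_radius_angstrom) -
                                   test_pts[i, ])^2)))
    expect_lt(abs(v_full[i] - (v_nuc + v_elec_quad)), 1e-3)
  }

  # near-nucleus masking
  expect_warning(
    vm <- esp_at(scf$hf_density_ao, scf$geometry, scf$basis,
                 rbind(c(0, 0, 0))),
    "masked")
  expect_true(is.na(vm))
})

test_that("dipole: zero cases, symmetry, and the charged origin-shift identity", {
  g <- geometry("C", matrix(0, 1, 3))
  bs <- build_basis(g)
  mu0 <- dipole_moment(matrix(0, 5, 5), g, bs)
  expect_equal(mu0$dipole_au, c(0, 0, 0), tolerance = 1e-14)

  scf <- fixture_system("h2", 2, 2)$scf
  mu_h2 <- dipole_moment(scf$hf_density_ao, scf$geometry, scf$basis)
  expect_lt(mu_h2$magnitude_debye, 1e-8)    # homonuclear: zero by symmetry

  # origin shift changes mu by exactly -(total charge) * shift
  h3 <- make_fixture("h3plus", with_scf = TRUE)
  s <- c(0.7, -1.1, 0.4)
  m1 <- dipole_moment(h3$scf$hf_density_ao, h3$geometry, h3$scf$basis)
  m2 <- dipole_moment(h3$scf$hf_density_ao, h3$geometry, h3$scf$basis,
                      origin = s)
  expect_equal(m2$dipole_au - m1$dipole_au, -1 * s, tolerance = 1e-10)
})

test_that("Mulliken analysis: symmetry zeros, completeness, charge sum", {
  scf <- fixture_system("h2", 2, 2)$scf
  mk <- mulliken(scf$hf_density_ao, scf$overlap, scf$geometry, scf$basis)
  expect_equal(unname(mk$charges), c(0, 0), tolerance = 1e-10)
  expect_equal(sum(mk$populations),
               sum(diag(scf$hf_density_ao %*% scf$overlap)),
               tolerance = 1e-10)
  h3 <- make_fixture("h3plus", with_scf = TRUE)
  mk3 <- mulliken(h3$scf$hf_density_ao, h3$scf$overlap, h3$geometry,
                  h3$scf$basis)
  expect_equal(sum(mk3$charges), 1, tolerance = 1e-8)
  expect_equal(sum(mk3$ao_populations), 2, tolerance = 1e-10)
})

test_that("critical points: lone-atom NCP and H2 bond midpoint BCP", {
  g1 <- geometry("H", matrix(0, 1, 3))
  bs1 <- .single_gaussian_basis(1.24)
  cp1 <- find_critical_points(matrix(1), bs1, g1)
  expect_equal(nrow(cp1), 1L)
  expect_equal(cp1$type, "NCP")
  expect_lt(sqrt(cp1$x^2 + cp1$y^2 + cp1$z^2), 1e-6)
  expect_true(all(c(cp1$lambda1, cp1$lambda2, cp1$lambda3) < 0))

  scf <- fixture_system("h2", 2, 2)$scf
  cps <- find_critical_points(scf$hf_density_ao, scf$basis, scf$geometry)
  expect_equal(sum(cps$type == "NCP"), 2L)
  bcp <- cps[cps$type == "BCP", ]
  expect_equal(nrow(bcp), 1L)
  mid <- colMeans(scf$geometry$coords) / bohr_radius_angstrom
  expect_lt(max(abs(c(bcp$x, bcp$y, bcp$z) - mid)), 1e-6)
  expect_lt(bcp$lambda2, 0)
  expect_gt(bcp$lambda3, 0)
  expect_equal(bcp$atoms, "H1-H2")
  # every reported CP satisfies the gradient condition
  for (i in seq_len(nrow(cps))) {
    gr <- density_at(scf$hf_density_ao, scf$basis,
                     matrix(c(cps$x[i], cps$y[i], cps$z[i]), 1),
                     deriv = 1L)$grad
    expect_lt(sqrt(sum(gr^2)), 1e-8)
  }
})

test_that("cube writer: hand-written reference layout and exact round trip", {
  g <- geometry("H", matrix(0, 1, 3))
  field <- structure(list(grid = grid_spec(c(0, 0, 0), diag(rep(0.5, 3)),
                                           c(2L, 2L, 2L)),
                          values = array(1:8, c(2, 2, 2))),
                     class = "scalar_field")
  tf <- tempfile(fileext = ".cube")
  write_cube(field, g, tf, comment1 = "c1", comment2 = "c2")
  expect_identical(readLines(tf), c(
    "c1", "c2",
    "    1    0.000000    0.000000    0.000000",
    "    2    0.500000    0.000000    0.000000",
    "    2    0.000000    0.500000    0.000000",
    "    2    0.000000    0.000000    0.500000",
    "    1    1.000000    0.000000    0.000000    0.000000",
    paste(sprintf("%14.6E", 1:6), collapse = " "),
    paste(sprintf("%14.6E", 7:8), collapse = " ")))

  rb <- read_cube(tf)
  expect_equal(rb$field$values, field$values + 0, tolerance = 1e-6)
  expect_equal(rb$Z, 1L)

  # round trip on a real density
  scf <- fixture_system("h2", 2, 2)$scf
  grid <- default_grid(scf$geometry, resolution = 0.4, padding = 2)
  f2 <- density_field(scf$hf_density_ao, scf$basis, grid)
  tf2 <- tempfile(fileext = ".cube")
  write_cube(f2, scf$geometry, tf2)
  rb2 <- read_cube(tf2)
  rel <- abs(rb2$field$values - f2$values) / pmax(abs(f2$values), 1e-12)
  expect_lt(max(rel), 1e-6)
  expect_equal(rb2$field$grid$counts, grid$counts)
})
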