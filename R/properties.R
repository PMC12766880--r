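# 1-RDM-derived molecular properties: electron density (with analytic
# derivatives), electrostatic potential, dipole moment, Mulliken populations
# and QTAIM critical points of the density topology.

#' Evaluate the electron density (and derivatives) at points
#'
#' `rho(r) = sum_{mu nu} gamma[mu nu] phi_mu(r) phi_nu(r)` with analytic
#' gradient and Hessian assembled from the analytic derivatives of the
#' contracted Gaussians.
#'
#' @param gamma AO density matrix.
#' @param basis basis description from [build_basis()] (or an
#'   `scf_reference$basis`).
#' @param points n x 3 matrix of evaluation points (Bohr).
#' @param deriv 0 = density only, 1 = + gradient, 2 = + Hessian.
#' @return list with `rho` (length n), and per `deriv`: `grad` (n x 3),
#'   `hessian` (n x 3 x 3).
#' @export
density_at <- function(gamma, basis, points, deriv = 0L) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(gamma) != basis$nao) stop("gamma/basis dimension mismatch")
  ev <- cpp_ao_eval(basis$shells, points, as.integer(deriv))
  phi <- ev$values                       # n x nao
  gphi <- phi %*% gamma                  # n x nao
  out <- list(rho = rowSums(gphi * phi))
  np <- nrow(points)
  if (deriv >= 1) {
    grad <- matrix(0, np, 3)
    for (k in 1:3) {
      dphi <- matrix(ev$grad[(k - 1) * np * basis$nao + seq_len(np * basis$nao)],
                     np, basis$nao)
      grad[, k] <- 2 * rowSums(gphi * dphi)
    }
    out$grad <- grad
  }
  if (deriv >= 2) {
    dphi <- lapply(1:3, function(k)
      matrix(ev$grad[(k - 1) * np * basis$nao + seq_len(np * basis$nao)],
             np, basis$nao))
    # hess components in order xx, xy, xz, yy, yz, zz
    hidx <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
    hess <- array(0, c(np, 3, 3))
    for (k in 1:6) {
      ddphi <- matrix(ev$hess[(k - 1) * np * basis$nao + seq_len(np * basis$nao)],
                      np, basis$nao)
      i <- hidx[k, 1]; j <- hidx[k, 2]
      v <- 2 * rowSums((dphi[[i]] %*% gamma) * dphi[[j]]) +
           2 * rowSums(gphi * ddphi)
      hess[, i, j] <- v
      hess[, j, i] <- v
    }
    out$hessian <- hess
  }
  out
}

#' Grid specification for scalar fields
#'
#' @param origin 3-vector (Bohr).
#' @param axes 3 x 3 matrix of step vectors (rows, Bohr).
#' @param counts 3 integers (points per axis, >= 2).
#' @export
grid_spec <- function(origin, axes, counts) {
  axes <- matrix(as.numeric(axes), 3, 3)
  stopifnot(all(counts >= 2), abs(det(axes)) > 1e-12)
  structure(list(origin = as.numeric(origin), axes = axes,
                 counts = as.integer(counts)), class = "grid_spec")
}

#' Default cube grid for a geometry
#'
#' Axis-aligned box: molecule bounding box padded by `padding` Bohr per side,
#' with isotropic step `resolution` (Bohr).
#'
#' @param geom a `vqerdm_geometry`.
#' @param resolution step length in Bohr (default 0.10).
#' @param padding padding per side in Bohr.
#' @export
default_grid <- function(geom, resolution = 0.10, padding = 4.0) {
  xyz <- angstrom_to_bohr(geom$coords)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / resolution)) + 1L)
  grid_spec(lo, diag(rep(resolution, 3)), counts)
}

#' All grid points of a grid_spec
#'
#' Points are ordered with the third axis fastest (cube-file layout).
#'
#' @param grid a `grid_spec`.
#' @return (prod(counts)) x 3 matrix of points (Bohr).
#' @export
grid_points <- function(grid) {
  i <- rep(seq_len(grid$counts[1]) - 1, each = grid$counts[2] * grid$counts[3])
  j <- rep(rep(seq_len(grid$counts[2]) - 1, each = grid$counts[3]),
           times = grid$counts[1])
  k <- rep(seq_len(grid$counts[3]) - 1, times = grid$counts[1] * grid$counts[2])
  sweep(cbind(i, j, k) %*% grid$axes, 2, grid$origin, `+`)
}

#' Electron density on a grid
#'
#' @param gamma AO density matrix.
#' @param basis basis description.
#' @param grid a `grid_spec`.
#' @param chunk evaluation chunk size (points per C++ call).
#' @return a `scalar_field` (list with `grid` and `values` 3-D array).
#' @export
density_field <- function(gamma, basis, grid, chunk = 50000L) {
  pts <- grid_points(grid)
  vals <- numeric(nrow(pts))
  for (s in split(seq_len(nrow(pts)), (seq_len(nrow(pts)) - 1) %/% chunk)) {
    vals[s] <- density_at(gamma, basis, pts[s, , drop = FALSE])$rho
  }
  structure(list(grid = grid,
                 values = array(vals, rev(grid$counts))),  # k fastest
            class = "scalar_field")
}

#' Electrostatic potential field
#'
#' `V(r) = sum_A Z_A / |r - R_A| - sum_{mu nu} gamma[mu nu] W_{mu nu}(r)`
#' where `W` are point-charge (nuclear-attraction-type) one-electron
#' integrals.  Grid points within 1e-6 Bohr of a nucleus are masked to `NA`
#' with a warning.
#'
#' @param gamma AO density matrix.
#' @param geom the molecular geometry.
#' @param basis basis description.
#' @param grid a `grid_spec`.
#' @param chunk points per integral batch.
#' @return a `scalar_field` of the potential (Hartree / e).
#' @export
esp_field <- function(gamma, geom, basis, grid, chunk = 2000L) {
  pts <- grid_points(grid)
  vals <- esp_at(gamma, geom, basis, pts, chunk = chunk)
  structure(list(grid = grid, values = array(vals, rev(grid$counts))),
            class = "scalar_field")
}

#' @rdname esp_field
#' @param points n x 3 matrix (Bohr).
#' @export
esp_at <- function(gamma, geom, basis, points, chunk = 2000L) {
  points <- matrix(as.numeric(points), ncol = 3)
  xyz <- angstrom_to_bohr(geom$coords)
  np <- nrow(points)
  vals <- numeric(np)
  masked <- logical(np)
  for (a in seq_len(nrow(xyz))) {
    d <- sqrt(colSums((t(points) - xyz[a, ])^2))
    masked <- masked | d < 1e-6
    vals <- vals + geom$Z[a] / pmax(d, 1e-300)
  }
  nao <- basis$nao
  for (s in split(seq_len(np), (seq_len(np) - 1) %/% chunk)) {
    W <- cpp_point_charge_ints(basis$shells, points[s, , drop = FALSE])
    Wm <- matrix(W, nao * nao, length(s))
    vals[s] <- vals[s] - as.vector(as.numeric(gamma) %*% Wm)
  }
  if (any(masked)) {
    warning(sprintf("%d grid point(s) within 1e-6 Bohr of a nucleus masked",
                    sum(masked)))
    vals[masked] <- NA_real_
  }
  vals
}

#' Dipole moment from an AO density
#'
#' `mu_x = -sum_{mu nu} gamma[mu nu] (nu|x|mu) + sum_A Z_A X_A` about the
#' given origin (all in atomic units), with the magnitude also reported in
#' Debye.  For a charged species the dipole depends on the origin; the
#' default is the coordinate origin of the supplied geometry.
#'
#' @param gamma AO density matrix.
#' @param geom the molecular geometry.
#' @param basis basis description.
#' @param origin gauge origin (Bohr).
#' @return list with `dipole_au` (3-vector), `dipole_debye`, `magnitude_au`,
#'   `magnitude_debye`, `origin`.
#' @export
dipole_moment <- function(gamma, geom, basis, origin = c(0, 0, 0)) {
  xyz <- angstrom_to_bohr(geom$coords)
  one <- cpp_one_electron(basis$shells, as.numeric(geom$Z), xyz,
                          as.numeric(origin))
  elec <- -c(sum(gamma * one$DX), sum(gamma * one$DY), sum(gamma * one$DZ))
  nuc <- colSums(geom$Z * sweep(xyz, 2, origin, `-`))
  mu <- elec + nuc
  list(dipole_au = mu, dipole_debye = mu * debye_per_au,
       magnitude_au = sqrt(sum(mu^2)),
       magnitude_debye = sqrt(sum(mu^2)) * debye_per_au, origin = origin)
}

#' Mulliken populations and charges
#'
#' `P_A = sum_{mu in A, nu} gamma[mu nu] S[nu mu]`, `q_A = Z_A - P_A`.
#' Also returns the per-AO populations (the diagonal of `gamma S`), which sum
#' to the electron count.
#'
#' @param gamma AO density matrix.
#' @param S AO overlap matrix.
#' @param geom the molecular geometry.
#' @param basis basis description (for the AO-to-atom map and labels).
#' @return list with `populations`, `charges` (per atom) and
#'   `ao_populations` (named per AO).
#' @export
mulliken <- function(gamma, S, geom, basis) {
  gs <- diag(gamma %*% S)
  pops <- vapply(seq_along(geom$Z),
                 function(a) sum(gs[basis$ao_atom == a]), numeric(1))
  list(populations = setNames(pops, paste0(geom$symbols, seq_along(geom$Z))),
       charges = setNames(geom$Z - pops,
                          paste0(geom$symbols, seq_along(geom$Z))),
       ao_populations = setNames(gs, basis$ao_labels))
}

#' Locate critical points of the electron density
#'
#' Newton-Raphson searches on the analytic density gradient/Hessian, seeded at
#' every nucleus and at the midpoint of every pair of nuclei closer than
#' `pair_cutoff` Bohr.  Converged roots (`||grad rho|| < grad_tol`) are
#' deduplicated within `dedup_tol` Bohr and classified by the Hessian
#' signature: NCP = three negative eigenvalues, BCP = two negative and one
#' positive.  Ring/cage signatures are labelled `"other"`.
#'
#' @param gamma AO density matrix.
#' @param basis basis description.
#' @param geom the molecular geometry.
#' @param pair_cutoff bond-seed distance cutoff (Bohr); the default reaches
#'   the stretched C-H bond paths of dissociating systems.
#' @param grad_tol convergence threshold on the gradient norm.
#' @param dedup_tol merge radius for duplicate roots (Bohr).
#' @param max_newton Newton iteration cap per seed.
#' @param rho_min density floor (e/a0^3); roots in the numerical far-field
#'   tail below this value are discarded as spurious.
#' @return data.frame with columns `type`, `x`, `y`, `z` (Bohr), `rho`,
#'   `laplacian`, `lambda1..3` (ascending), `atoms` (flanking nuclei for
#'   BCPs, own nucleus for NCPs).
#' @export
find_critical_points <- function(gamma, basis, geom, pair_cutoff = 4.5,
                                 grad_tol = 1e-8, dedup_tol = 1e-4,
                                 max_newton = 100L, rho_min = 1e-4) {
  xyz <- angstrom_to_bohr(geom$coords)
  n_at <- nrow(xyz)
  seeds <- xyz
  if (n_at >= 2) {
    for (i in seq_len(n_at - 1)) for (j in seq(i + 1, n_at)) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < pair_cutoff) {
        seeds <- rbind(seeds, (xyz[i, ] + xyz[j, ]) / 2)
      }
    }
  }
  roots <- list()
  for (s in seq_len(nrow(seeds))) {
    x <- seeds[s, ]
    ok <- FALSE
    for (it in seq_len(max_newton)) {
      ev <- density_at(gamma, basis, matrix(x, 1), deriv = 2L)
      g <- as.vector(ev$grad)
      H <- ev$hessian[1, , ]
      gn <- sqrt(sum(g^2))
      if (gn < grad_tol) { ok <- TRUE; break }
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      # trust-region style cap to keep Newton from jumping out of the basin
      sl <- sqrt(sum(step^2))
      if (sl > 0.5) step <- step * 0.5 / sl
      x <- x - step
      if (any(!is.finite(x)) || sqrt(sum(x^2)) > 1e3) break
    }
    if (ok) roots[[length(roots) + 1]] <- x
  }
  if (length(roots) == 0) {
    return(data.frame(type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), rho = numeric(0), laplacian = numeric(0),
                      lambda1 = numeric(0), lambda2 = numeric(0),
                      lambda3 = numeric(0), atoms = character(0)))
  }
  # deduplicate
  uniq <- list()
  for (r in roots) {
    if (!any(vapply(uniq, function(u) sqrt(sum((u - r)^2)) < dedup_tol,
                    logical(1)))) {
      uniq[[length(uniq) + 1]] <- r
    }
  }
  rows <- lapply(uniq, function(x) {
    ev <- density_at(gamma, basis, matrix(x, 1), deriv = 2L)
    if (ev$rho < rho_min) return(NULL)   # numerical far-field root
    lam <- sort(eigen(ev$hessian[1, , ], symmetric = TRUE)$values)
    nneg <- sum(lam < 0)
    type <- if (nneg == 3) "NCP" else if (nneg == 2) "BCP" else "other"
    d <- sqrt(colSums((t(xyz) - x)^2))
    atoms <- if (type == "NCP") {
      paste0(geom$symbols[which.min(d)], which.min(d))
    } else {
      # flanking pair: the two nuclei whose connecting segment the point sits
      # between (minimal perimeter excess d_A + d_B - d_AB); ties by index
      best <- c(1L, 2L); excess <- Inf
      for (i in seq_len(n_at - 1)) for (j in seq(i + 1, n_at)) {
        e <- d[i] + d[j] - sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (e < excess - 1e-12) { excess <- e; best <- c(i, j) }
      }
      paste(paste0(geom$symbols[best], best), collapse = "-")
    }
    data.frame(type = type, x = x[1], y = x[2], z = x[3], rho = ev$rho,
               laplacian = sum(diag(ev$hessian[1, , ])),
               lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
               atoms = atoms)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), rho = numeric(0), laplacian = numeric(0),
                      lambda1 = numeric(0), lambda2 = numeric(0),
                      lambda3 = numeric(0), atoms = character(0)))
  }
  out[order(out$type, out$atoms), , drop = FALSE]
}
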