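# Node/dof helpers mirroring the mesh numbering (0-based grid coords).
nid <- function(mesh, ix0, iy0) ix0 * (mesh$ny + 1L) + iy0 + 1L

test_that("assembly is linear in E and identical across homogeneous elements", {
  f <- substrate_homogeneous(50, extent = 10, spacing = 2.5)
  m <- fem_assemble(f)
  f2 <- substrate_homogeneous(100, extent = 10, spacing = 2.5)
  m2 <- fem_assemble(f2)
  expect_equal(as.matrix(m2$K), 2 * as.matrix(m$K), tolerance = 1e-12)
  # symmetry
  expect_lt(max(abs(as.matrix(m$K) - t(as.matrix(m$K)))), 1e-12)
})

test_that("the element matrix matches an independent fine-quadrature assembly", {
  # oracle: integrate B' C B over the reference square on a dense grid
  nu <- 0.45
  C0 <- matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
  ng <- 200
  pts <- (seq_len(ng) - 0.5) / ng * 2 - 1
  Kor <- matrix(0, 8, 8)
  for (xi in pts) for (eta in pts) {
    dNdx <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdy <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    B <- matrix(0, 3, 8)
    B[1, c(1, 3, 5, 7)] <- dNdx
    B[2, c(2, 4, 6, 8)] <- dNdy
    B[3, c(1, 3, 5, 7)] <- dNdy
    B[3, c(2, 4, 6, 8)] <- dNdx
    Kor <- Kor + t(B) %*% C0 %*% B * (2 / ng)^2
  }
  expect_equal(adhesim:::quad_unit_stiffness(nu), Kor, tolerance = 1e-4)
})

test_that("solve satisfies basic mechanics: zero load, symmetry, equilibrium", {
  f <- substrate_homogeneous(10, extent = 25, spacing = 2.5)
  mesh <- fem_assemble(f)
  z <- fem_solve(mesh, matrix(0, mesh$nnode, 2))
  expect_true(all(z == 0))

  # equal and opposite x-loads mirrored about the vertical midline give a
  # mirror-antisymmetric ux field
  loads <- matrix(0, mesh$nnode, 2)
  loads[nid(mesh, 3, 5), 1] <- 1
  loads[nid(mesh, 7, 5), 1] <- -1
  u <- fem_solve(mesh, loads)
  ux <- matrix(u[, 1], mesh$ny + 1L)  # (iy0+1, ix0+1)
  expect_equal(ux, -ux[, rev(seq_len(ncol(ux)))], tolerance = 1e-10)

  # global equilibrium: boundary reactions balance the applied load
  loads2 <- matrix(0, mesh$nnode, 2)
  loads2[nid(mesh, 5, 4), ] <- c(2.5, -1.5)
  u2 <- fem_solve(mesh, loads2)
  uvec <- as.vector(t(u2))
  resid <- as.numeric(mesh$K %*% uvec)
  fvec <- as.vector(t(loads2))
  reactions <- resid - fvec
  expect_lt(abs(sum(reactions[seq(1, length(resid), 2)]) + sum(loads2[, 1])),
            1e-8 * max(1, sum(abs(loads2))))
  expect_lt(abs(sum(reactions[seq(2, length(resid), 2)]) + sum(loads2[, 2])),
            1e-8 * max(1, sum(abs(loads2))))
})

test_that("solution scales linearly with load and inversely with stiffness", {
  f <- substrate_homogeneous(10, extent = 25, spacing = 2.5)
  mesh <- fem_assemble(f)
  loads <- matrix(0, mesh$nnode, 2)
  loads[nid(mesh, 5, 5), ] <- c(1, 0.5)
  u1 <- fem_solve(mesh, loads)
  u2 <- fem_solve(mesh, 2 * loads)
  expect_equal(u2, 2 * u1, tolerance = 1e-12)
  mesh4 <- fem_assemble(substrate_homogeneous(40, extent = 25, spacing = 2.5))
  u4 <- fem_solve(mesh4, loads)
  expect_equal(u4, u1 / 4, tolerance = 1e-10)
})

test_that("sparse solver agrees with a dense oracle on a small mesh", {
  f <- substrate_uniform_noise(20, 10, extent = 25, spacing = 2.5, seed = 5)
  mesh <- fem_assemble(f)
  set.seed(8)
  loads <- matrix(0, mesh$nnode, 2)
  interior <- setdiff(seq_len(mesh$nnode),
                      unique(ceiling(setdiff(seq_len(2 * mesh$nnode),
                                             mesh$free_dof) / 2)))
  loads[interior, ] <- rnorm(2 * length(interior), sd = 0.5)
  u <- fem_solve(mesh, loads)
  Kd <- as.matrix(mesh$K)[mesh$free_dof, mesh$free_dof]
  fvec <- as.vector(t(loads))[mesh$free_dof]
  u_or <- solve(Kd, fvec)
  expect_equal(as.vector(t(u))[mesh$free_dof], u_or, tolerance = 1e-10)
})

test_that("a uniform uniaxial stress state is reproduced to 1e-8", {
  # left edge held in x, bottom-left corner also in y; uniform traction on
  # the right edge; lateral edges free -> sigma_xx = sigma0 everywhere
  E0 <- 10; sigma0 <- 0.2
  f <- substrate_homogeneous(E0, extent = 25, spacing = 2.5, nu = 0.45,
                             thickness = 10)
  nx <- f$nx; ny <- f$ny; nny <- ny + 1L
  nnode <- (nx + 1L) * nny
  gx <- rep(0:nx, each = nny); gy <- rep(0:ny, times = nx + 1L)
  fixed <- c(2L * which(gx == 0L) - 1L,      # ux = 0 on the left edge
             2L * which(gx == 0L & gy == 0L)) # pin one uy
  mesh <- fem_assemble(f, fixed_dofs = fixed)
  # consistent nodal loads for uniform edge traction sigma0 * h
  loads <- matrix(0, nnode, 2)
  right <- which(gx == nx)
  w <- ifelse(gy[right] == 0L | gy[right] == ny, 0.5, 1)
  loads[right, 1] <- sigma0 * f$thickness * f$spacing * w
  u <- fem_solve(mesh, loads)
  st <- fem_element_stress(mesh, u)
  expect_lt(max(abs(st$sxx - sigma0)) / sigma0, 1e-8)
  expect_lt(max(abs(st$syy)) / sigma0, 1e-8)
  expect_lt(max(abs(st$sxy)) / sigma0, 1e-8)
  # and the analytic strain: exx = sigma0 / E
  exx <- (u[nid(mesh, nx, 0L), 1] - u[nid(mesh, 0L, 0L), 1]) / f$extent[1]
  expect_equal(unname(exx), sigma0 / E0, tolerance = 1e-8)
})

test_that("element stress transforms correctly for canonical states", {
  f <- substrate_homogeneous(10, extent = 25, spacing = 2.5, nu = 0.3)
  mesh <- fem_assemble(f)
  nny <- mesh$ny + 1L
  gx <- rep(0:mesh$nx, each = nny); gy <- rep(0:mesh$ny, times = mesh$nx + 1L)

  # rigid-body translation -> zero stress
  u_rigid <- cbind(rep(0.3, mesh$nnode), rep(-0.1, mesh$nnode))
  st <- fem_element_stress(mesh, u_rigid)
  expect_lt(max(abs(st$sxx), abs(st$syy), abs(st$sxy)), 1e-12)

  # prescribed equi-biaxial strain -> hydrostatic stress sigma0 everywhere
  eps0 <- 0.01
  u_bi <- cbind(eps0 * gx * f$spacing, eps0 * gy * f$spacing)
  st2 <- fem_element_stress(mesh, u_bi)
  sig0 <- 10 / (1 - 0.3^2) * (1 + 0.3) * eps0
  expect_equal(as.vector(st2$hydrostatic), rep(sig0, mesh$nx * mesh$ny),
               tolerance = 1e-10)
})

test_that("the adhesion stimulus keeps only tensile hydrostatic stress", {
  st <- structure(list(hydrostatic = matrix(c(-3, 0, 0.4, 2), 2, 2)),
                  class = "stress_field")
  g <- stress_stimulus(st)
  expect_equal(as.vector(g), c(0, 0, 0.4, 2))
})

test_that("missing boundary conditions are refused", {
  f <- substrate_homogeneous(10, extent = 10, spacing = 2.5)
  expect_error(fem_assemble(f, fixed_dofs = integer(0)), "singular")
})
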