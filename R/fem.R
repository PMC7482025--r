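#' Plane-stress finite-element model of the substrate
#'
#' The substrate is meshed with one bilinear quadrilateral element per
#' lattice site, sharing the grid of the stiffness field and the CPM
#' lattice one-to-one. Displacements live on the (nx+1) x (ny+1) node
#' grid; all domain-boundary nodes are fixed (the gel is glued to the
#' dish). Element stiffness follows plane stress,
#' `C = E/(1-nu^2) * [[1, nu, 0], [nu, 1, 0], [0, 0, (1-nu)/2]]`,
#' integrated with 2x2 Gauss quadrature; for square elements the element
#' matrix is size-independent and scales linearly with `E * thickness`.
#'
#' `fem_assemble()` factors the constrained stiffness matrix once (sparse
#' Cholesky); within a simulation the stiffness field never changes, so
#' each Monte Carlo step only triggers a new triangular solve.
#'
#' @param field a [stiffness_field][substrate] object.
#' @param fixed_dofs optional integer vector of constrained degrees of
#'   freedom (node `n` owns dofs `2n-1` = ux and `2n` = uy), overriding
#'   the default clamp of every domain-boundary node; at least one dof
#'   must remain fixed or the system is singular.
#' @return `fem_assemble()` returns a `substrate_mesh` carrying the global
#'   stiffness matrix, its Cholesky factor restricted to free degrees of
#'   freedom, and the node/element bookkeeping.
#' @export
fem_assemble <- function(field, fixed_dofs = NULL) {
  stopifnot(inherits(field, "stiffness_field"))
  nx <- field$nx; ny <- field$ny
  nnx <- nx + 1L; nny <- ny + 1L
  nnode <- nnx * nny
  nid <- function(ix0, iy0) ix0 * nny + iy0 + 1L  # 0-based grid coords

  ex <- rep(seq_len(nx) - 1L, each = ny)
  ey <- rep(seq_len(ny) - 1L, times = nx)
  enode <- cbind(sw = nid(ex, ey), se = nid(ex + 1L, ey),
                 ne = nid(ex + 1L, ey + 1L), nw = nid(ex, ey + 1L))
  K0 <- quad_unit_stiffness(field$nu)  # 8x8, scale by E*h
  Ee <- as.vector(field$E)             # element moduli, site order

  # dof index per element: (ux, uy) interleaved, 8 per element
  edof <- matrix(0L, nrow(enode), 8L)
  edof[, c(1, 3, 5, 7)] <- 2L * enode - 1L
  edof[, c(2, 4, 6, 8)] <- 2L * enode
  idx <- rep(seq_len(8L), times = 8L)
  jdx <- rep(seq_len(8L), each = 8L)
  i_all <- as.vector(edof[, idx])
  j_all <- as.vector(edof[, jdx])
  x_all <- as.vector(outer(Ee * field$thickness, as.vector(K0)))
  K <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all,
                            dims = c(2L * nnode, 2L * nnode))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  gx <- rep(0:nx, each = nny); gy <- rep(0:ny, times = nnx)
  if (is.null(fixed_dofs)) {
    fixed_node <- gx == 0L | gx == nx | gy == 0L | gy == ny
    fixed_dofs <- which(rep(fixed_node, each = 2L))
  }
  if (length(fixed_dofs) == 0)
    stop("no boundary condition: the stiffness matrix is singular",
         call. = FALSE)
  free_dof <- setdiff(seq_len(2L * nnode), as.integer(fixed_dofs))
  K_ff <- K[free_dof, free_dof]
  ch <- Matrix::Cholesky(K_ff, LDL = FALSE, perm = TRUE)

  structure(
    list(K = K, chol = ch, free_dof = free_dof, enode = enode,
         node_x = gx * field$spacing, node_y = gy * field$spacing,
         nnode = nnode, nx = nx, ny = ny,
         spacing = field$spacing, nu = field$nu,
         thickness = field$thickness, element_E = field$E),
    class = "substrate_mesh")
}

# 8x8 bilinear-quad plane-stress stiffness for a square element with
# E = 1, thickness = 1; node order SW, SE, NE, NW, dofs (ux, uy) per node.
quad_unit_stiffness <- function(nu) {
  C0 <- matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    # derivatives on the reference square, chain rule cancels element size
    dNdx <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdy <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    B <- matrix(0, 3, 8)
    B[1, c(1, 3, 5, 7)] <- dNdx
    B[2, c(2, 4, 6, 8)] <- dNdy
    B[3, c(1, 3, 5, 7)] <- dNdy
    B[3, c(2, 4, 6, 8)] <- dNdx
    K <- K + t(B) %*% C0 %*% B
  }
  K
}

#' Solve the substrate displacement field under nodal loads
#'
#' @param mesh a `substrate_mesh` from [fem_assemble()].
#' @param loads nodal force matrix (`nnode` x 2, nN); loads on fixed
#'   boundary nodes are ignored (absorbed by the support).
#' @return displacement matrix (`nnode` x 2, um).
#' @export
fem_solve <- function(mesh, loads) {
  stopifnot(inherits(mesh, "substrate_mesh"),
            is.matrix(loads), nrow(loads) == mesh$nnode, ncol(loads) == 2)
  f <- numeric(2L * mesh$nnode)
  f[seq(1, by = 2, length.out = mesh$nnode)] <- loads[, 1]
  f[seq(2, by = 2, length.out = mesh$nnode)] <- loads[, 2]
  u <- numeric(2L * mesh$nnode)
  sol <- Matrix::solve(mesh$chol, f[mesh$free_dof])
  u[mesh$free_dof] <- as.numeric(sol)
  if (!all(is.finite(u))) stop("FEM solve failed (non-finite displacements)")
  cbind(ux = u[seq(1, by = 2, length.out = mesh$nnode)],
        uy = u[seq(2, by = 2, length.out = mesh$nnode)])
}

#' Planar stress per element
#'
#' Evaluates the strain-displacement relation at each element center and
#' applies the plane-stress constitutive law, returning the in-plane
#' stress tensor and the hydrostatic (planar) stress
#' `sigma_h = (sigma_xx + sigma_yy) / 2`.
#'
#' @param mesh a `substrate_mesh`.
#' @param u displacement matrix from [fem_solve()].
#' @return A `stress_field`: list of `ny` x `nx` matrices `sxx`, `syy`,
#'   `sxy`, `hydrostatic` (kPa).
#' @export
fem_element_stress <- function(mesh, u) {
  stopifnot(inherits(mesh, "substrate_mesh"))
  h <- 1 / (2 * mesh$spacing)
  en <- mesh$enode
  ux <- matrix(u[en, 1], nrow(en), 4); uy <- matrix(u[en, 2], nrow(en), 4)
  cx <- c(-1, 1, 1, -1) * h  # dN/dx at center, node order SW SE NE NW
  cy <- c(-1, -1, 1, 1) * h
  exx <- drop(ux %*% cx)
  eyy <- drop(uy %*% cy)
  gxy <- drop(ux %*% cy + uy %*% cx)
  Ee <- as.vector(mesh$element_E); nu <- mesh$nu
  fac <- Ee / (1 - nu^2)
  sxx <- fac * (exx + nu * eyy)
  syy <- fac * (eyy + nu * exx)
  sxy <- fac * (1 - nu) / 2 * gxy
  shape <- c(mesh$ny, mesh$nx)
  structure(list(
    sxx = matrix(sxx, shape[1], shape[2]),
    syy = matrix(syy, shape[1], shape[2]),
    sxy = matrix(sxy, shape[1], shape[2]),
    hydrostatic = matrix((sxx + syy) / 2, shape[1], shape[2])),
    class = "stress_field")
}

#' Mechanical stimulus sensed by a focal adhesion
#'
#' The tensile part of the planar (hydrostatic) stress at the adhesion's
#' element, `g = max(sigma_h, 0)`. The reinforcement pathway (talin
#' stretching exposing vinculin-binding sites) is a tension response, so
#' compressive stress contributes nothing. Under centripetal cell
#' traction the substrate is compressed beneath the cell body and
#' tensile in a narrow ring at and beyond the strongly pulling rim --
#' precisely under protrusions, which is what makes the feedback
#' pole-selective on elongating cells.
#'
#' @param stress a `stress_field` from [fem_element_stress()].
#' @param sites optional linear site indices; default all sites.
#' @return stimulus g (kPa, non-negative), same shape as the request.
#' @export
stress_stimulus <- function(stress, sites = NULL) {
  stopifnot(inherits(stress, "stress_field"))
  g <- pmax(stress$hydrostatic, 0)
  if (is.null(sites)) g else g[sites]
}

#' Distribute per-site adhesion forces to mesh nodes
#'
#' Forces act at element centers, where all four bilinear shape functions
#' equal 1/4: each corner node receives a quarter of the site force.
#'
#' @param mesh a `substrate_mesh`.
#' @param sites linear site (= element) indices carrying adhesions.
#' @param fx,fy force components per site (nN).
#' @return nodal load matrix suitable for [fem_solve()].
#' @export
node_loads_from_sites <- function(mesh, sites, fx, fy) {
  loads <- matrix(0, mesh$nnode, 2)
  en <- mesh$enode[sites, , drop = FALSE]
  for (c in 1:4) {
    loads[, 1] <- loads[, 1] +
      as.vector(tabulate_weighted(en[, c], fx / 4, mesh$nnode))
    loads[, 2] <- loads[, 2] +
      as.vector(tabulate_weighted(en[, c], fy / 4, mesh$nnode))
  }
  loads
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
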