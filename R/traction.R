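#' Cell centroid
#'
#' Arithmetic mean of the occupied site centers, in um.
#'
#' @param spin integer lattice matrix (0 = medium, 1 = cell).
#' @param spacing lattice spacing (um).
#' @return centroid `c(x, y)` in um.
#' @export
cell_centroid <- function(spin, spacing = 2.5) {
  occ <- which(spin == 1L)
  if (length(occ) == 0) stop("cell is empty", call. = FALSE)
  xy <- site_centers(occ, nrow(spin), spacing)
  colMeans(xy)
}

# site centers (um) for linear indices on an ny-row lattice
site_centers <- function(idx, ny, spacing) {
  ix <- ((idx - 1L) %/% ny) + 1L
  iy <- ((idx - 1L) %% ny) + 1L
  cbind(x = (ix - 0.5) * spacing, y = (iy - 0.5) * spacing)
}

#' Stall forces from the first-moment-of-area traction model
#'
#' The cell acts as a single contractile unit: every occupied site is
#' pulled toward the cell centroid with stall force
#' `Fs(i) = mu * (rbar - r_i)`, i.e. magnitude proportional to the
#' distance from the centroid. The force field has zero net force and
#' zero net torque about the centroid for any cell shape.
#'
#' @param spin integer lattice matrix (0/1).
#' @param mu traction coefficient (nN/um), default 0.06.
#' @param spacing lattice spacing (um).
#' @return list with `sites` (linear indices of occupied sites), `fx`,
#'   `fy` (force components, nN), `fmag`, `centroid`, and `mu`.
#' @export
stall_forces <- function(spin, mu = 0.06, spacing = 2.5) {
  occ <- which(spin == 1L)
  if (length(occ) == 0) stop("cell is empty", call. = FALSE)
  xy <- site_centers(occ, nrow(spin), spacing)
  ctr <- colMeans(xy)
  dx <- as.numeric(ctr[[1]] - xy[, 1])
  dy <- as.numeric(ctr[[2]] - xy[, 2])
  list(sites = occ, fx = mu * dx, fy = mu * dy,
       fmag = mu * sqrt(dx^2 + dy^2), centroid = ctr, mu = mu)
}
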