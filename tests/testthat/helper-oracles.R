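# Shared fixtures and independent oracles for the test suite.

# Full CPM Hamiltonian evaluated from scratch (independent of the
# engine's incremental form). Interface energy over von Neumann bonds
# with out-of-domain neighbours counting as medium; no adhesion barrier
# (that term is a kinetic barrier on retraction, not a state energy).
brute_force_H <- function(spin, params, spacing = 2.5) {
  ny <- nrow(spin); nx <- ncol(spin)
  pad <- matrix(0L, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- spin
  mism <- sum(pad[, -1] != pad[, -(nx + 2)]) + sum(pad[-1, ] != pad[-(ny + 2), ])
  area <- sum(spin == 1L) * spacing^2
  params$J_cm * mism +
    params$lambda_area * (area - params$A_target)^2 -
    params$lambda_C * sum(spin == 1L)
}

# random single-component blob grown from a seed site
random_blob <- function(nx, ny, n_sites, seed = 1) {
  set.seed(seed)
  spin <- matrix(0L, ny, nx)
  cur <- c(ceiling(nx / 2), ceiling(ny / 2))
  spin[cur[2], cur[1]] <- 1L
  while (sum(spin) < n_sites) {
    occ <- which(spin == 1L)
    k <- occ[sample.int(length(occ), 1)]
    ix <- ((k - 1) %/% ny) + 1; iy <- ((k - 1) %% ny) + 1
    d <- sample(4, 1)
    nb <- switch(d, c(ix + 1, iy), c(ix - 1, iy), c(ix, iy + 1), c(ix, iy - 1))
    if (nb[1] >= 1 && nb[1] <= nx && nb[2] >= 1 && nb[2] <= ny)
      spin[nb[2], nb[1]] <- 1L
  }
  spin
}

# is the cell a single 4-connected component?
single_component <- function(spin) {
  occ <- which(spin == 1L)
  if (length(occ) <= 1) return(TRUE)
  ny <- nrow(spin)
  lab <- matrix(0L, nrow(spin), ncol(spin))
  queue <- occ[1]; lab[occ[1]] <- 1L
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    ix <- ((k - 1) %/% ny) + 1; iy <- ((k - 1) %% ny) + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      jx <- ix + d[1]; jy <- iy + d[2]
      if (jx < 1 || jy < 1 || jx > ncol(spin) || jy > nrow(spin)) next
      j <- (jx - 1) * ny + jy
      if (spin[j] == 1L && lab[j] == 0L) { lab[j] <- 1L; queue <- c(queue, j) }
    }
  }
  sum(lab) == length(occ)
}

# rasterized shapes on a small lattice
disc_spin <- function(r_sites = 10, pad = 4) {
  n <- 2 * (r_sites + pad) + 1
  ctr <- r_sites + pad + 1
  spin <- matrix(0L, n, n)
  for (ix in 1:n) for (iy in 1:n)
    if ((ix - ctr)^2 + (iy - ctr)^2 <= r_sites^2) spin[iy, ix] <- 1L
  spin
}

ellipse_spin <- function(a_sites, b_sites, pad = 4) {
  nx <- 2 * (a_sites + pad) + 1; ny <- 2 * (b_sites + pad) + 1
  cx <- a_sites + pad + 1; cy <- b_sites + pad + 1
  spin <- matrix(0L, ny, nx)
  for (ix in 1:nx) for (iy in 1:ny)
    if (((ix - cx) / a_sites)^2 + ((iy - cy) / b_sites)^2 <= 1) spin[iy, ix] <- 1L
  spin
}

# small simulation configuration used across tests
tiny_config <- function(E = 50, variant = "1", n_mcs = 20, seed = 1,
                        extent = 100, ...) {
  sim_config(substrate_homogeneous(E, extent = extent),
             variant = variant, n_mcs = n_mcs, seed = seed, ...)
}
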