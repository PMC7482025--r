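make_params <- function(A_target, ...) {
  p <- cpm_params(...)
  p$A_target <- A_target
  p
}

test_that("the incremental Hamiltonian matches a brute-force energy difference", {
  set.seed(10)
  for (trial in 1:20) {
    spin <- random_blob(8, 8, sample(8:20, 1), seed = trial)
    params <- make_params(A_target = sum(spin) * 6.25 * 1.2,
                          T = 10, J_cm = 3, lambda_area = 2e-3,
                          lambda_C = 0.4, eps_bond = 0)
    # pick an interface pair at random
    occ <- which(spin == 1L)
    repeat {
      k <- sample(64, 1)
      ix <- ((k - 1) %/% 8) + 1; iy <- ((k - 1) %% 8) + 1
      s_new <- 1L - spin[iy, ix]
      nbr_ok <- FALSE  # must neighbour an opposite spin (interface move)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1),
                     c(1, -1), c(-1, 1), c(-1, -1))) {
        jx <- ix + d[1]; jy <- iy + d[2]
        if (jx >= 1 && jy >= 1 && jx <= 8 && jy <= 8 &&
            spin[jy, jx] == s_new) nbr_ok <- TRUE
      }
      if (nbr_ok) break
    }
    N <- matrix(0L, 8, 8); F <- matrix(0, 8, 8); w <- matrix(1, 8, 8)
    dH <- hamiltonian_delta(spin, N, F, w, c(ix, iy), s_new, params, 2.5)
    after <- spin; after[iy, ix] <- s_new
    expect_equal(dH,
                 brute_force_H(after, params) - brute_force_H(spin, params),
                 tolerance = 1e-10)
  }
})

test_that("the detachment barrier applies to mature loaded adhesions only", {
  spin <- disc_spin(4)
  params <- make_params(A_target = sum(spin) * 6.25,
                        J_cm = 3, lambda_area = 0, lambda_C = 0,
                        eps_bond = 0.01)
  N <- matrix(0L, nrow(spin), ncol(spin))
  F <- matrix(0, nrow(spin), ncol(spin))
  w <- matrix(1, nrow(spin), ncol(spin))
  # boundary cell site
  occ <- which(spin == 1L)
  ny <- nrow(spin)
  edge <- occ[vapply(occ, function(k) {
    ix <- ((k - 1) %/% ny) + 1; iy <- ((k - 1) %% ny) + 1
    spin[iy, ix + 1] == 0L
  }, logical(1))][1]
  ix <- ((edge - 1) %/% ny) + 1; iy <- ((edge - 1) %% ny) + 1

  base <- hamiltonian_delta(spin, N, F, w, c(ix, iy), 0L, params, 2.5)
  # mature loaded cluster: barrier eps * N * w = 0.01 * 100 * 1.5 = 1.5
  N[edge] <- 100L; F[edge] <- 1; w[edge] <- 1.5
  expect_equal(hamiltonian_delta(spin, N, F, w, c(ix, iy), 0L, params, 2.5),
               base + 1.5)
  # unloaded cluster of the same size: no barrier
  F[edge] <- 0
  expect_equal(hamiltonian_delta(spin, N, F, w, c(ix, iy), 0L, params, 2.5),
               base)
  # loaded but still nascent (N = N0): no barrier
  N[edge] <- 50L; F[edge] <- 1
  expect_equal(hamiltonian_delta(spin, N, F, w, c(ix, iy), 0L, params, 2.5),
               base)
})

test_that("acceptance statistics follow the Boltzmann rule", {
  spin <- disc_spin(6)
  params <- make_params(A_target = sum(spin) * 6.25, T = 8, J_cm = 4,
                        lambda_area = 1e-3, lambda_C = 0.3, eps_bond = 0)
  N <- matrix(0L, nrow(spin), ncol(spin))
  F <- matrix(0, nrow(spin), ncol(spin))
  w <- matrix(1, nrow(spin), ncol(spin))
  pool <- list(N_free = 1e5, N_total = 1e5)
  set.seed(99)
  dh <- acc <- numeric(0)
  st <- list(spin = spin, N = N, F = F, pool = pool)
  for (i in 1:120) {
    res <- run_mcs(st$spin, st$N, st$F, w, params, st$pool,
                   record_attempts = TRUE)
    dh <- c(dh, res$attempt_dH)
    acc <- c(acc, res$attempt_accept)
    st <- list(spin = res$spin, N = res$N, F = res$F, pool = res$pool)
  }
  # connectivity-vetoed attempts carry no energy; drop them
  acc <- acc[!is.na(dh)]; dh <- dh[!is.na(dh)]
  # bin positive-dH attempts; compare empirical acceptance with exp(-dH/T)
  pos <- dh > 0
  expect_true(all(acc[!pos] == 1))  # dH <= 0 always accepted
  bins <- split(seq_along(dh)[pos], cut(dh[pos], breaks = 5))
  for (b in bins) {
    if (length(b) < 50) next
    p_hat <- mean(acc[b])
    p_exp <- mean(exp(-dh[b] / params$T))
    se <- sqrt(p_exp * (1 - p_exp) / length(b))
    expect_lt(abs(p_hat - p_exp), 3.5 * se + 1e-9)
  }
})

test_that("one MCS performs as many attempts as there are interface sites", {
  spin <- disc_spin(6)
  params <- make_params(A_target = sum(spin) * 6.25)
  z <- matrix(0L, nrow(spin), ncol(spin))
  set.seed(3)
  res <- run_mcs(spin, z, matrix(0, nrow(spin), ncol(spin)),
                 matrix(1, nrow(spin), ncol(spin)), params,
                 list(N_free = 1e5, N_total = 1e5), record_attempts = TRUE)
  expect_equal(res$attempts, cpp_interface_count(spin))
  expect_equal(length(res$attempt_dH), res$attempts)
})

test_that("the cell stays a single connected component through many MCS", {
  cfg <- tiny_config(E = 50, n_mcs = 60, seed = 5)
  st <- initialize_run(cfg)
  for (i in 1:60) {
    st <- sim_step(st)
    if (i %% 20 == 0) expect_true(single_component(st$spin))
  }
  expect_true(single_component(st$spin))
})

test_that("a stronger adhesion barrier monotonically suppresses retraction", {
  spin <- disc_spin(6)
  ny <- nrow(spin)
  Nmat <- matrix(0L, ny, ncol(spin))
  Fmat <- matrix(0, ny, ncol(spin))
  occ <- which(spin == 1L)
  Nmat[occ] <- 200L; Fmat[occ] <- 1   # mature loaded adhesions everywhere
  w <- matrix(1, ny, ncol(spin))
  pool <- list(N_free = 1e5, N_total = 1e6)
  n_ret <- vapply(c(0, 0.1, 0.6), function(eps) {
    params <- make_params(A_target = sum(spin) * 6.25, T = 10, J_cm = 2,
                          lambda_area = 2e-3, lambda_C = 0, eps_bond = eps)
    set.seed(42)
    tot <- 0L
    st <- list(spin = spin, N = Nmat, F = Fmat, pool = pool)
    for (i in 1:10) {
      res <- run_mcs(st$spin, st$N, st$F, w, params, st$pool)
      tot <- tot + res$n_ret
      st <- list(spin = res$spin, N = res$N, F = res$F, pool = res$pool)
    }
    tot
  }, numeric(1))
  expect_true(all(diff(n_ret) < 0))
})

test_that("accepted moves manage adhesions and the pool correctly", {
  spin <- disc_spin(5)
  params <- make_params(A_target = sum(spin) * 6.25, T = 20, J_cm = 1,
                        lambda_area = 0, lambda_C = 0, eps_bond = 0)
  ny <- nrow(spin)
  Nmat <- matrix(0L, ny, ncol(spin))
  occ <- which(spin == 1L)
  Nmat[occ] <- 60L
  pool <- list(N_free = 1000L, N_total = 1000L + 60L * length(occ))
  set.seed(11)
  res <- run_mcs(spin, Nmat, matrix(0, ny, ncol(spin)),
                 matrix(1, ny, ncol(spin)), params, pool, N_seed = 50)
  # conservation, new sites seeded at N_seed, vacated sites emptied
  expect_equal(sum(res$N) + res$pool$N_free, sum(Nmat) + pool$N_free)
  expect_true(all(res$N[res$spin == 0L] == 0L))
  new_sites <- which(res$spin == 1L & spin == 0L)
  if (length(new_sites)) expect_true(all(res$N[new_sites] == 50L))
})
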