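test_that("the catch-slip unbinding rate has the documented shape", {
  cs <- catch_slip_params()
  expect_equal(koff(0, cs), cs$k_s + cs$k_c)

  # closed-form lifetime optimum against a numeric minimizer
  f_star <- koff_argmin(cs)
  f_num <- stats::optimize(function(f) koff(f, cs), c(0, 200))$minimum
  expect_equal(f_num, f_star, tolerance = 1e-4)

  # defaults are calibrated so the single-bond lifetime peaks near 30 pN
  grid <- seq(0, 100, by = 0.1)
  expect_equal(grid[which.max(1 / koff(grid, cs))], 30, tolerance = 2)

  expect_error(koff(-1, cs), "non-negative")
  expect_warning(catch_slip_params(k_s = 10, k_c = 0.001), "maximum")
})

test_that("force build-up matches its closed form and stiffness ordering", {
  bp <- buildup_params(ell = 0.2, E_series = 1e9)  # negligible series term
  # stall: zero rate at F = Fs
  expect_equal(buildup_rate(10, 10, 50, bp), 0)
  expect_error(buildup_rate(11, 10, 50, bp), "lie in")

  # closed form at one time constant: F = Fs * (1 - exp(-1))
  E <- 10; Fs <- 10
  E_eff <- E * bp$E_series / (E + bp$E_series)
  tau <- Fs / (E_eff * bp$ell * bp$v0)
  expect_equal(force_buildup(tau, Fs, E, bp), Fs * (1 - exp(-1)),
               tolerance = 1e-12)

  # independent RK4 integration of dF/dt agrees to 1e-6
  h <- tau / 2000
  Fnum <- 0
  for (i in 1:2000) {
    k1 <- buildup_rate(Fnum, Fs, E, bp)
    k2 <- buildup_rate(min(Fs, Fnum + h / 2 * k1), Fs, E, bp)
    k3 <- buildup_rate(min(Fs, Fnum + h / 2 * k2), Fs, E, bp)
    k4 <- buildup_rate(min(Fs, Fnum + h * k3), Fs, E, bp)
    Fnum <- Fnum + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(Fnum, force_buildup(tau, Fs, E, bp), tolerance = 1e-6)

  # doubling E halves tau: strictly more force on stiffer substrate
  expect_gt(force_buildup(5, Fs, 2 * E, bp), force_buildup(5, Fs, E, bp))

  # the series linkage caps the build-up rate at high substrate stiffness
  bp2 <- buildup_params(ell = 0.2, E_series = 150)
  expect_lt(buildup_rate(0, 10, 1e6, bp2) / (150 * 0.2 * 0.1), 1.0001)

  expect_equal(force_buildup(c(1, 5), 0, 50, bp), c(0, 0))
})

test_that("cluster kinetics conserve integrins and decay without binding", {
  cs <- catch_slip_params(); bp <- buildup_params()
  # with an empty pool, dynamics is pure decay
  set.seed(1)
  res <- cluster_step(100, 0, list(N_free = 0, N_total = 1000), 0.1, bp, cs)
  expect_lte(res$N, 100)
  expect_equal(res$N + res$pool$N_free, 100)

  # unloaded clusters decay toward extinction (soft-substrate regime)
  set.seed(2)
  N <- 50; pool <- list(N_free = 1e5, N_total = 2e5)
  for (i in 1:300) {
    res <- cluster_step(N, 0, pool, 0.1, bp, cs)
    N <- res$N; pool <- res$pool
  }
  expect_lt(N, 50)

  # conservation over a long random trajectory
  set.seed(3)
  N <- 80; pool <- list(N_free = 500, N_total = 1000)
  for (i in 1:500) {
    res <- cluster_step(N, 0.8, pool, 0.1, bp, cs)
    N <- res$N; pool <- res$pool
    expect_identical(N + pool$N_free, 580L + 0L)
  }
})

test_that("long-time cluster size fluctuates around the mean-field root", {
  cs <- catch_slip_params(); bp <- buildup_params()
  F <- 2.5  # nN, held constant; large pool so binding is unthrottled
  pool0 <- list(N_free = 1e6, N_total = 1e6)
  # mean-field root: gamma = N * koff(1000 * F / N)
  root <- stats::uniroot(function(N) bp$gamma - N * koff(1000 * F / N, cs),
                         c(60, 5000))$root
  set.seed(4)
  sizes <- numeric(0)
  N <- round(root); pool <- pool0
  for (i in 1:4000) {
    res <- cluster_step(N, F, pool, 0.1, bp, cs)
    N <- res$N; pool <- pool0  # reset pool: isolated cluster
    if (i > 500) sizes <- c(sizes, N)
  }
  expect_equal(mean(sizes), root, tolerance = 0.05)
})

test_that("nascent pruning removes sub-threshold clusters and refunds bonds", {
  N <- matrix(c(0L, 49L, 50L, 120L), 2, 2)
  pool <- list(N_free = 100, N_total = 1000)
  pr <- prune_nascent(N, pool, N0 = 50)
  expect_equal(as.vector(pr$N), c(0L, 0L, 50L, 120L))
  expect_equal(pr$pool$N_free, 149)
  expect_equal(pr$n_pruned, 1L)
  expect_equal(sum(pr$N) + pr$pool$N_free, sum(N) + pool$N_free)
})

test_that("reinforcement saturates between 1 and 1 + p", {
  expect_equal(reinforcement(0, p = 2, sigma_h = 0.5), 1)
  expect_equal(reinforcement(0.5, p = 2, sigma_h = 0.5), 2)  # half-saturation
  expect_equal(reinforcement(1e9, p = 2, sigma_h = 0.5), 3, tolerance = 1e-6)
  g <- seq(0, 10, by = 0.1)
  w <- reinforcement(g, p = 1.5, sigma_h = 0.3)
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 1 & w < 2.5))
  expect_error(reinforcement(-1), "non-negative")
})

test_that("the model variants route the feedback to the right quantity", {
  g <- c(0, 0.5, 10); Fs <- c(1, 2, 3)
  v1 <- apply_feedback("1", g, Fs, p = 1, sigma_h = 0.5)
  expect_equal(v1$w, rep(1, 3)); expect_equal(v1$Fs_eff, Fs)
  v21 <- apply_feedback("2.1", g, Fs, p = 1, sigma_h = 0.5)
  expect_equal(v21$w, reinforcement(g, 1, 0.5)); expect_equal(v21$Fs_eff, Fs)
  v22 <- apply_feedback("2.2", g, Fs, p = 1, sigma_h = 0.5)
  expect_equal(v22$w, rep(1, 3))
  expect_equal(v22$Fs_eff[2], 1.5 * Fs[2])  # stall force x1.5 at g = sigma_h
  expect_error(apply_feedback("3", g, Fs), "variant")
})
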