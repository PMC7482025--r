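#' Catch-slip bond parameters
#'
#' A focal adhesion is a cluster of integrin catch-slip bonds whose
#' per-bond unbinding rate
#' `koff(f) = k_s * exp(f/F_slip) + k_c * exp(-f/F_catch)`
#' first drops with per-bond tension f (catch pathway) and then rises
#' again (slip pathway). The defaults are calibrated so the single-bond
#' lifetime `1/koff` peaks near f = 30 pN, the loading optimum reported
#' for alpha5-beta1 integrin, with a lifetime gain of roughly two orders
#' of magnitude between the unloaded and the optimally loaded bond. The
#' closed-form lifetime optimum is
#' `f* = F_slip*F_catch/(F_slip+F_catch) * log(k_c*F_slip/(k_s*F_catch))`.
#'
#' @param k_s slip unbinding prefactor (1/s).
#' @param k_c catch unbinding prefactor (1/s); `k_c + k_s` is the
#'   unloaded unbinding rate.
#' @param F_slip slip force scale (pN).
#' @param F_catch catch force scale (pN).
#' @return object of class `catch_slip_params`.
#' @export
catch_slip_params <- function(k_s = 0.0156, k_c = 3,
                              F_slip = 18, F_catch = 7) {
  stopifnot(k_s > 0, k_c > 0, F_slip > 0, F_catch > 0)
  if (k_c * F_slip <= k_s * F_catch)
    warning("no interior lifetime maximum: k_c*F_slip <= k_s*F_catch")
  structure(list(k_s = k_s, k_c = k_c, F_slip = F_slip, F_catch = F_catch),
            class = "catch_slip_params")
}

#' Per-bond unbinding rate of a catch-slip bond
#'
#' @param f per-bond tension (pN), non-negative, vectorized.
#' @param params a [catch_slip_params()] object.
#' @return unbinding rate (1/s).
#' @export
koff <- function(f, params = catch_slip_params()) {
  if (any(f < 0)) stop("per-bond force must be non-negative", call. = FALSE)
  params$k_s * exp(f / params$F_slip) + params$k_c * exp(-f / params$F_catch)
}

#' Force at which the bond lifetime peaks (closed form)
#'
#' @inheritParams koff
#' @return optimal per-bond tension (pN).
#' @export
koff_argmin <- function(params = catch_slip_params()) {
  with(params,
       F_slip * F_catch / (F_slip + F_catch) * log(k_c * F_slip / (k_s * F_catch)))
}

#' Force build-up parameters
#'
#' Traction force on an adhesion builds towards its stall force at a rate
#' set by the local substrate stiffness: the substrate acts as a spring of
#' stiffness `E * ell`, in series with the intracellular linkage
#' `E_series * ell`, loaded at the unloaded myosin motor velocity `v0`:
#' `dF/dt = E_eff*ell*v0 * (1 - F/Fs)` with
#' `E_eff = E*E_series/(E + E_series)`, and the closed form
#' `F(t) = Fs * (1 - exp(-t/tau))` with `tau = Fs / (E_eff*ell*v0)`.
#' Forces therefore reach stall within a protrusion lifetime (`t_FA`) on
#' stiff substrates but not on soft ones -- the core stiffness-sensing
#' mechanism -- while the build-up rate saturates once the substrate is
#' much stiffer than the cell's own contractile machinery.
#'
#' @param v0 myosin motor velocity (um/s; default 0.1 = 100 nm/s).
#' @param ell adhesion coupling length (um) converting Young's modulus to
#'   a spring constant; calibrated so build-up is near-complete within
#'   `t_fa` at 50 kPa and far from complete at 1 kPa.
#' @param t_fa force build-up window between Monte Carlo steps (s).
#' @param dt ODE substep (s); `t_fa/dt` must be a whole number.
#' @param gamma cluster growth rate (bonds/s): integrins bind at this
#'   constant rate while free integrins are plentiful.
#' @param pool_sat reserve fraction of the integrin pool; binding slows
#'   in proportion to the free fraction only once it falls below this
#'   value, so adhesion growth is pool-limited only in well-spread cells.
#' @param E_series stiffness of the intracellular linkage (stress fiber
#'   plus adaptor proteins, kPa) acting in series with the substrate:
#'   the loading spring is `E*E_series/(E + E_series)`, so the force
#'   build-up rate saturates on substrates much stiffer than the cell's
#'   own machinery instead of diverging.
#' @return object of class `buildup_params`.
#' @export
buildup_params <- function(v0 = 0.1, ell = 0.3, t_fa = 10, dt = 0.1,
                           gamma = 13, pool_sat = 0.4, E_series = 150) {
  stopifnot(v0 > 0, ell > 0, t_fa > 0, dt > 0, gamma > 0,
            pool_sat > 0, pool_sat <= 1, E_series > 0)
  nsub <- t_fa / dt
  if (abs(nsub - round(nsub)) > 1e-8)
    stop("t_fa/dt must be a positive integer", call. = FALSE)
  structure(list(v0 = v0, ell = ell, t_fa = t_fa, dt = dt, gamma = gamma,
                 pool_sat = pool_sat, E_series = E_series),
            class = "buildup_params")
}

#' Traction force build-up rate and closed form
#'
#' @param F current force (nN), `0 <= F <= Fs_eff`.
#' @param Fs_eff effective stall force (nN); 0 gives zero rate.
#' @param E_local local Young's modulus (kPa).
#' @param params a [buildup_params()] object.
#' @return `buildup_rate()`: dF/dt in nN/s. `force_buildup()`: F(t) in nN
#'   starting from `F0`.
#' @export
buildup_rate <- function(F, Fs_eff, E_local, params = buildup_params()) {
  if (any(F < 0) || any(F > Fs_eff + 1e-12))
    stop("F must lie in [0, Fs_eff]", call. = FALSE)
  E_eff <- E_local * params$E_series / (E_local + params$E_series)
  ifelse(Fs_eff > 0, E_eff * params$ell * params$v0 * (1 - F / Fs_eff), 0)
}

#' @rdname buildup_rate
#' @param t elapsed time (s).
#' @param F0 force at t = 0 (nN).
#' @export
force_buildup <- function(t, Fs_eff, E_local, params = buildup_params(), F0 = 0) {
  if (Fs_eff <= 0) return(rep(0, length(t)))
  E_eff <- E_local * params$E_series / (E_local + params$E_series)
  tau <- Fs_eff / (E_eff * params$ell * params$v0)
  Fs_eff + (F0 - Fs_eff) * exp(-t / tau)
}

#' One birth-death (tau-leap) substep of a single adhesion cluster
#'
#' Bond gains are Poisson with mean `b(N_free) * dt` (clamped by the
#' free pool), where the binding rate `b` equals `gamma` while the free
#' pool fraction exceeds `pool_sat` and declines in proportion to the
#' free fraction below that reserve. Bond losses are binomial with
#' per-bond unbinding probability `1 - exp(-koff(F/N) * dt)`. The
#' expected change therefore matches the mean-field rate equation
#' `dN/dt = b - N * koff(F/N)` while retaining the demographic noise
#' that lets marginal clusters go extinct. Added bonds are debited from
#' the free-integrin pool and lost bonds credited back:
#' `N_free + sum(N)` is conserved exactly.
#'
#' @param N current bond count (integer).
#' @param F current cluster force (nN); per-bond tension is `1000*F/N` pN.
#' @param pool list with integer `N_free` and `N_total`.
#' @param dt substep (s).
#' @param bp [buildup_params()] (only `gamma` is used).
#' @param cs [catch_slip_params()].
#' @return list with updated `N` and `pool`.
#' @export
cluster_step <- function(N, F, pool, dt, bp = buildup_params(),
                         cs = catch_slip_params()) {
  res <- cpp_cluster_step(as.integer(N), F, as.integer(pool$N_free),
                          pool$N_total, dt, bp$gamma,
                          cs$k_s, cs$k_c, cs$F_slip, cs$F_catch,
                          bp$pool_sat)
  list(N = res[1], pool = list(N_free = res[2], N_total = pool$N_total))
}

#' Remove nascent adhesions that failed to mature
#'
#' Clusters that end a build-up window below the nascent-adhesion
#' threshold `N0` break apart; their bonds return to the free pool.
#'
#' @param N integer vector/matrix of bond counts.
#' @param pool list with `N_free`, `N_total`.
#' @param N0 nascent adhesion threshold (bonds), default 50.
#' @return list with pruned `N`, updated `pool`, and `n_pruned`.
#' @export
prune_nascent <- function(N, pool, N0 = 50) {
  doomed <- N > 0L & N < N0
  returned <- sum(N[doomed])
  N[doomed] <- 0L
  list(N = N, pool = list(N_free = pool$N_free + returned,
                          N_total = pool$N_total),
       n_pruned = sum(doomed))
}

#' Stress-dependent adhesion reinforcement factor
#'
#' Saturating response of adhesion stability to the tensile hydrostatic
#' stress stimulus g: `w = 1 + p * g / (sigma_h + g)`, bounded in
#' `[1, 1 + p)`.
#'
#' @param g stimulus (kPa), non-negative, vectorized.
#' @param p feedback strength (dimensionless).
#' @param sigma_h half-saturation stress (kPa).
#' @return reinforcement factor w.
#' @export
reinforcement <- function(g, p = 2, sigma_h = 0.5) {
  stopifnot(p >= 0, sigma_h > 0)
  if (any(g < 0)) stop("stimulus g must be non-negative", call. = FALSE)
  1 + p * g / (sigma_h + g)
}

#' Route the stress feedback according to the model variant
#'
#' Variant "1" has no feedback; "2.1" reinforces the CPM detachment
#' energy barrier (`w`); "2.2" scales the stall force instead.
#'
#' @param variant one of "1", "2.1", "2.2".
#' @param g stimulus (kPa), vectorized over sites.
#' @param Fs base stall forces (nN), same length as `g`.
#' @param p,sigma_h feedback parameters, see [reinforcement()].
#' @return list with `w` (barrier multiplier) and `Fs_eff`.
#' @export
apply_feedback <- function(variant, g, Fs, p = 2, sigma_h = 0.5) {
  variant <- as.character(variant)
  if (!variant %in% c("1", "2.1", "2.2"))
    stop("unknown model variant: ", variant, call. = FALSE)
  switch(variant,
    "1"   = list(w = rep(1, length(g)), Fs_eff = Fs),
    "2.1" = list(w = reinforcement(g, p, sigma_h), Fs_eff = Fs),
    "2.2" = list(w = rep(1, length(g)),
                 Fs_eff = Fs * reinforcement(g, p, sigma_h)))
}
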