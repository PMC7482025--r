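#' Cellular Potts model parameters
#'
#' The cell is a single connected set of lattice sites evolving by
#' energy-biased copy attempts at cellular temperature `T`. The
#' Hamiltonian combines a cell-medium interface energy (`J_cm` per
#' von Neumann boundary segment), an elastic area constraint
#' `lambda_area * (A - A_target)^2`, a substrate-adhesion (spreading)
#' energy `-lambda_C` per occupied site, and -- the mechanosensitive
#' ingredient -- a detachment barrier `eps_bond * N * w` that a
#' retraction must pay to rip a focal adhesion of `N` bonds (reinforced
#' by `w`) off the substrate.
#'
#' @param T cellular temperature (energy units); high enough that
#'   protrusions form freely and elongated shapes stay motile.
#' @param J_cm cell-medium interface energy per boundary segment.
#' @param lambda_area area-constraint stiffness (energy/um^4).
#' @param A_target target area (um^2); `NULL` defers to the simulation,
#'   which sets it 20 percent above the initial cell area so spreading is
#'   driven by adhesion rather than the area constraint.
#' @param lambda_C substrate-adhesion energy per site.
#' @param eps_bond detachment work per integrin bond.
#' @return object of class `cpm_params`.
#' @export
cpm_params <- function(T = 10, J_cm = 12, lambda_area = 3e-4,
                       A_target = NULL, lambda_C = 0.25, eps_bond = 0.5) {
  stopifnot(T > 0, J_cm >= 0, lambda_area >= 0, eps_bond >= 0)
  structure(list(T = T, J_cm = J_cm, lambda_area = lambda_area,
                 A_target = A_target, lambda_C = lambda_C,
                 eps_bond = eps_bond),
            class = "cpm_params")
}

#' Energy change of a single copy attempt
#'
#' Exposes the engine's incremental Hamiltonian for one source-target
#' pair (used by the Monte Carlo kernel, and testable against a
#' brute-force evaluation of the full Hamiltonian).
#'
#' @param spin integer lattice matrix (0/1).
#' @param N integer bond-count matrix (same shape).
#' @param F force matrix (nN, same shape); the detachment barrier
#'   `eps_bond * N * w` applies only to load-bearing adhesions (F > 0) --
#'   an unloaded nascent cluster has no tension-engaged catch bonds and
#'   detaches freely.
#' @param w reinforcement matrix (same shape).
#' @param target `c(ix, iy)` 1-based column/row coordinates of the site
#'   to be overwritten.
#' @param s_src spin value copied into the target (must differ).
#' @param params a [cpm_params()] object with `A_target` resolved.
#' @param spacing lattice spacing (um).
#' @return Delta H (energy units).
#' @export
hamiltonian_delta <- function(spin, N, F, w, target, s_src, params,
                              spacing = 2.5, N0 = 50) {
  stopifnot(!is.null(params$A_target))
  area <- sum(spin == 1L) * spacing^2
  cpp_delta_h(spin, as.numeric(N), as.numeric(F), as.numeric(w),
              target[1] - 1L, target[2] - 1L, as.integer(s_src),
              params$J_cm, params$lambda_area, params$A_target,
              params$lambda_C, params$eps_bond, spacing, area,
              as.integer(N0))
}

#' Run one Monte Carlo step
#'
#' Performs as many copy attempts as there are interface sites, sampling
#' source-target Moore pairs uniformly from the interface and accepting
#' with the Boltzmann rule `min(1, exp(-Delta H / T))`. Accepted
#' extensions seed a nascent adhesion of `N_seed` bonds (or fewer if the
#' pool is short); accepted retractions destroy the site's adhesion and
#' return its bonds. Retractions that would locally fragment the cell
#' are rejected outright.
#'
#' @inheritParams hamiltonian_delta
#' @param F force matrix (nN), zeroed at sites that change hands.
#' @param pool list with `N_free`, `N_total`.
#' @param N_seed bonds seeded on a fresh protrusion (default 50).
#' @param N0 nascent threshold: only clusters with `N > N0` anchor.
#' @param record_attempts if `TRUE`, also return per-attempt
#'   `(Delta H, accepted)` pairs for acceptance-statistics checks.
#' @return list with updated `spin`, `N`, `F`, `pool`, `area`, counts of
#'   accepted extensions/retractions, and optionally the attempt log.
#' @export
run_mcs <- function(spin, N, F, w, params, pool, N_seed = 50,
                    spacing = 2.5, N0 = 50, record_attempts = FALSE) {
  stopifnot(!is.null(params$A_target))
  res <- cpp_run_mcs(spin, N, F, as.numeric(w),
                     params$T, params$J_cm, params$lambda_area,
                     params$A_target, params$lambda_C, params$eps_bond,
                     spacing, as.integer(N_seed),
                     as.integer(pool$N_free), as.integer(N0),
                     record_attempts)
  res$pool <- list(N_free = res$N_free, N_total = pool$N_total)
  res
}
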