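#' Simulation configuration
#'
#' Bundles everything a run needs: the substrate, the model variant, the
#' parameter blocks of the CPM, the adhesion kinetics and the traction
#' model, run length and seeding. Variant "1" couples the CPM to the
#' adhesion dynamics only; variants "2.1" and "2.2" additionally solve
#' the substrate plane-stress problem every Monte Carlo step and feed the
#' tensile hydrostatic stress back onto the adhesions (detachment-energy
#' reinforcement and stall-force scaling, respectively).
#'
#' One Monte Carlo step corresponds to `t_fa` seconds of physical time
#' (default 10 s), so 2000 MCS is roughly 5.5 h and 10,000 MCS roughly
#' 28 h.
#'
#' @param substrate a [stiffness_field][substrate].
#' @param variant model variant: "1", "2.1" or "2.2".
#' @param n_mcs number of Monte Carlo steps.
#' @param seed integer RNG seed; the whole run is reproducible from
#'   (config, seed).
#' @param cell_radius initial disc radius (um); the default 28 um gives
#'   an initial area of about 2500 um^2.
#' @param cell_center initial centroid `c(x, y)` in um; default is the
#'   domain center.
#' @param cpm a [cpm_params()] block.
#' @param cs a [catch_slip_params()] block.
#' @param bp a [buildup_params()] block.
#' @param mu traction coefficient (nN/um), see [stall_forces()].
#' @param p,sigma_h stress-feedback parameters, see [reinforcement()].
#' @param N0 nascent adhesion threshold (bonds).
#' @param N_seed bonds seeded on a new protrusion (default `N0`).
#' @param N_total size of the free-integrin pool.
#' @param snapshot_interval store lattice snapshots every this many MCS
#'   (0 disables).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(substrate, variant = "1", n_mcs = 2000, seed = 1,
                       cell_radius = 28, cell_center = NULL,
                       cpm = cpm_params(), cs = catch_slip_params(),
                       bp = buildup_params(), mu = 0.06,
                       p = 2, sigma_h = 0.5,
                       N0 = 50, N_seed = N0, N_total = 2e5,
                       snapshot_interval = 0) {
  stopifnot(inherits(substrate, "stiffness_field"),
            inherits(cpm, "cpm_params"), inherits(cs, "catch_slip_params"),
            inherits(bp, "buildup_params"))
  variant <- as.character(variant)
  if (!variant %in% c("1", "2.1", "2.2"))
    stop("variant must be one of '1', '2.1', '2.2'", call. = FALSE)
  if (n_mcs < 0 || mu < 0 || p < 0 || sigma_h <= 0 || N0 < 1 ||
      N_seed < 0 || N_total < N_seed)
    stop("invalid simulation parameter", call. = FALSE)
  if (is.null(cell_center)) cell_center <- substrate$extent / 2
  if (any(cell_center - cell_radius < 0) ||
      any(cell_center + cell_radius > substrate$extent))
    stop("initial cell overlaps the domain boundary", call. = FALSE)
  structure(list(substrate = substrate, variant = variant,
                 n_mcs = as.integer(n_mcs), seed = as.integer(seed),
                 cell_radius = cell_radius, cell_center = cell_center,
                 cpm = cpm, cs = cs, bp = bp, mu = mu,
                 p = p, sigma_h = sigma_h, N0 = as.integer(N0),
                 N_seed = as.integer(N_seed), N_total = as.integer(N_total),
                 snapshot_interval = as.integer(snapshot_interval)),
            class = "sim_config")
}

#' Initialize a run state
#'
#' Rasterizes a disc-shaped cell at the configured center, seeds every
#' occupied site with a nascent adhesion of `N_seed` bonds at zero force
#' (debited from the integrin pool), resolves the CPM target area
#' (initial area + 20 percent unless set explicitly), and seeds the RNG.
#'
#' @param config a [sim_config()].
#' @return a `run_state` list.
#' @export
initialize_run <- function(config) {
  set.seed(config$seed)
  sub <- config$substrate
  nx <- sub$nx; ny <- sub$ny; dx <- sub$spacing
  cx <- (seq_len(nx) - 0.5) * dx
  cy <- (seq_len(ny) - 0.5) * dx
  inside <- outer(cy, cx, function(y, x)
    (x - config$cell_center[1])^2 + (y - config$cell_center[2])^2 <=
      config$cell_radius^2)
  spin <- matrix(0L, ny, nx)
  spin[inside] <- 1L
  if (!any(inside)) stop("initial cell radius too small for the lattice")
  occ <- which(spin == 1L)
  N <- matrix(0L, ny, nx)
  per_site <- config$N_seed
  N[occ] <- per_site
  pool <- list(N_free = config$N_total - per_site * length(occ),
               N_total = config$N_total)
  if (pool$N_free < 0) stop("integrin pool too small to seed initial cell")
  cpm <- config$cpm
  if (is.null(cpm$A_target)) cpm$A_target <- 1.2 * length(occ) * dx^2
  mesh <- NULL
  if (config$variant != "1") mesh <- fem_assemble(sub)
  list(spin = spin, N = N, F = matrix(0, ny, nx),
       w = matrix(1, ny, nx), g = matrix(0, ny, nx),
       pool = pool, cpm = cpm, mesh = mesh, stress = NULL,
       mcs = 0L, fem_calls = 0L, area = length(occ) * dx^2,
       config = config)
}

#' Advance the simulation by one Monte Carlo step
#'
#' Executes the per-MCS loop: (1) stall forces from the current shape
#' (first moment of area); (2) force build-up jointly with cluster
#' kinetics for `t_fa` seconds (stall forces scaled by the previous
#' step's stress in variant 2.2); (3) pruning of clusters below the
#' nascent threshold; (4) in variant 2, the plane-stress solve and the
#' stress feedback; (5) one CPM Monte Carlo step.
#'
#' @param state a `run_state` from [initialize_run()].
#' @return updated state.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  sub <- cfg$substrate
  dx <- sub$spacing
  occ <- which(state$spin == 1L)
  if (length(occ) == 0) stop("cell went extinct at MCS ", state$mcs)
  xy <- site_centers(occ, sub$ny, dx)
  ctr <- colMeans(xy)
  ux <- ctr[[1]] - xy[, 1]; uy <- ctr[[2]] - xy[, 2]
  dist <- sqrt(ux^2 + uy^2)
  Fs <- cfg$mu * dist

  fb_pre <- apply_feedback(cfg$variant, state$g[occ], Fs, cfg$p, cfg$sigma_h)
  Fs_eff <- fb_pre$Fs_eff

  res <- cpp_fa_window(occ - 1L, state$N, state$F, Fs_eff, sub$E[occ],
                       cfg$bp$ell, cfg$bp$v0, cfg$bp$t_fa, cfg$bp$dt,
                       cfg$bp$gamma, cfg$N_total,
                       as.integer(state$pool$N_free),
                       cfg$cs$k_s, cfg$cs$k_c, cfg$cs$F_slip, cfg$cs$F_catch,
                       cfg$bp$pool_sat, cfg$bp$E_series)
  state$N <- res$N
  state$F <- res$F
  state$pool$N_free <- res$N_free

  pr <- prune_nascent(state$N, state$pool, cfg$N0)
  state$N <- pr$N
  state$pool <- pr$pool
  state$F[state$N == 0L] <- 0

  if (cfg$variant != "1") {
    fa <- which(state$N > 0L)
    if (length(fa) > 0) {
      xyf <- site_centers(fa, sub$ny, dx)
      dfx <- ctr[[1]] - xyf[, 1]; dfy <- ctr[[2]] - xyf[, 2]
      dd <- sqrt(dfx^2 + dfy^2)
      fx <- ifelse(dd > 0, state$F[fa] * dfx / dd, 0)
      fy <- ifelse(dd > 0, state$F[fa] * dfy / dd, 0)
      loads <- node_loads_from_sites(state$mesh, fa, fx, fy)
      u <- fem_solve(state$mesh, loads)
      state$stress <- fem_element_stress(state$mesh, u)
      state$g <- matrix(stress_stimulus(state$stress), sub$ny, sub$nx)
    } else {
      state$g <- matrix(0, sub$ny, sub$nx)
    }
    state$fem_calls <- state$fem_calls + 1L
    fb <- apply_feedback(cfg$variant, as.vector(state$g),
                         rep(1, length(state$g)), cfg$p, cfg$sigma_h)
    state$w <- matrix(fb$w, sub$ny, sub$nx)
  }

  mc <- run_mcs(state$spin, state$N, state$F, state$w, state$cpm,
                state$pool, N_seed = cfg$N_seed, spacing = dx, N0 = cfg$N0)
  state$spin <- mc$spin
  state$N <- mc$N
  state$F <- mc$F
  state$pool <- mc$pool
  state$area <- mc$area
  state$mcs <- state$mcs + 1L
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulation
#'
#' @param config a [sim_config()].
#' @param progress print a progress line every 500 MCS.
#' @return list of class `sim_result` with `morphometrics` (one row per
#'   MCS including the initial state), the final `state`, and
#'   `snapshots` (lattice copies at the configured interval).
#' @export
run_simulation <- function(config, progress = FALSE) {
  state <- initialize_run(config)
  n <- config$n_mcs
  morpho <- vector("list", n + 1L)
  morpho[[1]] <- morpho_row(state)
  snaps <- list()
  if (config$snapshot_interval > 0) snaps[["0"]] <- snapshot_of(state)
  for (i in seq_len(n)) {
    state <- sim_step(state)
    morpho[[i + 1L]] <- morpho_row(state)
    if (config$snapshot_interval > 0 && i %% config$snapshot_interval == 0)
      snaps[[as.character(i)]] <- snapshot_of(state)
    if (progress && i %% 500 == 0)
      message(sprintf("MCS %d / %d: area %.0f um^2", i, n, state$area))
  }
  structure(list(morphometrics = do.call(rbind, morpho),
                 state = state, snapshots = snaps, config = config),
            class = "sim_result")
}

morpho_row <- function(state) {
  cfg <- state$config
  spin <- state$spin
  occ <- which(spin == 1L)
  ctr <- colMeans(site_centers(occ, nrow(spin), cfg$substrate$spacing))
  Nv <- state$N[state$N > 0L]
  data.frame(
    mcs = state$mcs,
    time_s = state$mcs * cfg$bp$t_fa,
    area_um2 = length(occ) * cfg$substrate$spacing^2,
    eccentricity = eccentricity(spin, cfg$substrate$spacing),
    centroid_x = ctr[[1]], centroid_y = ctr[[2]],
    n_clusters = length(Nv),
    median_N = if (length(Nv)) stats::median(Nv) else NA_real_,
    total_F = sum(state$F))
}

snapshot_of <- function(state) {
  list(mcs = state$mcs, spin = state$spin, N = state$N, F = state$F,
       hydrostatic = if (!is.null(state$stress)) state$stress$hydrostatic)
}

#' @export
print.sim_result <- function(x, ...) {
  m <- x$morphometrics
  cat(sprintf("<sim_result> model %s, %d MCS, seed %d\n",
              x$config$variant, x$config$n_mcs, x$config$seed))
  cat(sprintf("  final area %.0f um^2, eccentricity %.2f, %d clusters\n",
              utils::tail(m$area_um2, 1), utils::tail(m$eccentricity, 1),
              utils::tail(m$n_clusters, 1)))
  invisible(x)
}

#' Run a replicate ensemble
#'
#' Replicate `i` uses seed `config$seed + i - 1`.
#'
#' @param config a [sim_config()].
#' @param n_rep number of replicates.
#' @return list of `sim_result` objects.
#' @export
run_ensemble <- function(config, n_rep = 5) {
  lapply(seq_len(n_rep), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    run_simulation(cfg)
  })
}

#' Write run outputs to a directory
#'
#' Writes `morphometrics.csv`, per-snapshot cluster tables
#' (`clusters_<mcs>.csv`: site, x, y, N, F), snapshot grids
#' (`snapshot_<mcs>.csv`: cell mask as an integer grid) and PNG renders
#' (cell mask, adhesion sizes and, for variant 2, the hydrostatic-stress
#' color ramp), plus a `run_meta.json` with seed and parameters.
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if needed).
#' @param png also render PNG snapshots.
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, dir, png = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$morphometrics,
                   file.path(dir, "morphometrics.csv"), row.names = FALSE)
  cfg <- result$config
  for (nm in names(result$snapshots)) {
    sn <- result$snapshots[[nm]]
    fa <- which(sn$N > 0L)
    xy <- site_centers(fa, nrow(sn$spin), cfg$substrate$spacing)
    ctr <- cell_centroid(sn$spin, cfg$substrate$spacing)
    dxv <- as.numeric(ctr[[1]] - xy[, 1]); dyv <- as.numeric(ctr[[2]] - xy[, 2])
    dd <- sqrt(dxv^2 + dyv^2)
    utils::write.csv(
      data.frame(site = fa, x = xy[, 1], y = xy[, 2],
                 N = sn$N[fa], F = sn$F[fa],
                 Fx = ifelse(dd > 0, sn$F[fa] * dxv / dd, 0),
                 Fy = ifelse(dd > 0, sn$F[fa] * dyv / dd, 0)),
      file.path(dir, sprintf("clusters_%s.csv", nm)), row.names = FALSE)
    utils::write.table(sn$spin, file.path(dir, sprintf("snapshot_%s.csv", nm)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    if (png) render_snapshot(sn, file.path(dir, sprintf("snapshot_%s.png", nm)))
  }
  meta <- list(seed = cfg$seed, variant = cfg$variant, n_mcs = cfg$n_mcs,
               spacing = cfg$substrate$spacing, extent = cfg$substrate$extent,
               mu = cfg$mu, p = cfg$p, sigma_h = cfg$sigma_h,
               N0 = cfg$N0, N_total = cfg$N_total,
               cpm = unclass(cfg$cpm), catch_slip = unclass(cfg$cs),
               buildup = unclass(cfg$bp),
               package_version = as.character(utils::packageVersion("adhesim")))
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

# cell mask with FA-size overlay; hydrostatic stress as background ramp
render_snapshot <- function(sn, path) {
  grDevices::png(path, width = 600, height = 600)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  if (!is.null(sn$hydrostatic)) {
    rng <- range(sn$hydrostatic)
    graphics::image(t(sn$hydrostatic), col = grDevices::hcl.colors(64, "Blue-Red 2"),
                    axes = FALSE, main = sprintf("MCS %d", sn$mcs))
    graphics::image(t(sn$spin), col = c(NA, grDevices::adjustcolor("grey30", 0.35)),
                    add = TRUE)
  } else {
    graphics::image(t(sn$spin), col = c("white", "grey70"), axes = FALSE,
                    main = sprintf("MCS %d", sn$mcs))
  }
  fa <- which(sn$N > 0L)
  if (length(fa)) {
    ny <- nrow(sn$spin)
    ix <- ((fa - 1L) %/% ny) + 1L
    iy <- ((fa - 1L) %% ny) + 1L
    graphics::points((ix - 0.5) / ncol(sn$spin), (iy - 0.5) / ny,
                     pch = 16, col = "darkgreen",
                     cex = 0.2 + sn$N[fa] / 400)
  }
  invisible(path)
}
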