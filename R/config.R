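#' Read and write simulation configurations
#'
#' Configurations are flat YAML files with one block per parameter
#' group. Unknown keys are rejected with an error naming the offending
#' key; omitted keys take the package defaults, so a minimal file needs
#' only the model variant and a substrate block. A round trip through
#' [save_config()] and [load_config()] reproduces the configuration
#' exactly.
#'
#' @param path file path.
#' @return `load_config()` returns a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' @rdname load_config
#' @param config a [sim_config()].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

config_keys <- list(
  top = c("variant", "n_mcs", "seed", "substrate", "cell", "cpm",
          "catch_slip", "buildup", "traction", "feedback", "adhesion",
          "snapshot_interval"),
  substrate = c("type", "E0", "E_min", "slope", "amplitude", "period",
                "axis", "extent", "spacing", "nu", "thickness", "seed"),
  cell = c("radius", "center"),
  cpm = c("T", "J_cm", "lambda_area", "A_target", "lambda_C", "eps_bond"),
  catch_slip = c("k_s", "k_c", "F_slip", "F_catch"),
  buildup = c("v0", "ell", "t_fa", "dt", "gamma", "pool_sat", "E_series"),
  traction = c("mu"),
  feedback = c("p", "sigma_h"),
  adhesion = c("N0", "N_seed", "N_total"))

check_keys <- function(x, allowed, block) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key%s in %s block: %s",
                 if (length(bad) > 1) "s" else "", block,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(x)
}

check_positive <- function(x, nm) {
  if (!is.null(x) && (!is.numeric(x) || any(x <= 0)))
    stop(sprintf("parameter `%s` must be positive", nm), call. = FALSE)
  x
}

config_from_list <- function(raw) {
  check_keys(raw, config_keys$top, "top-level")
  sub <- raw$substrate
  if (is.null(sub) || is.null(sub$type))
    stop("config needs a substrate block with a `type`", call. = FALSE)
  check_keys(sub, config_keys$substrate, "substrate")
  geo <- list(extent = sub$extent %||% 500, spacing = sub$spacing %||% 2.5,
              nu = sub$nu %||% 0.45, thickness = sub$thickness %||% 10)
  field <- switch(sub$type,
    homogeneous = substrate_homogeneous(
      check_positive(sub$E0, "E0") %||% stop_key("E0"), geo$extent,
      geo$spacing, geo$nu, geo$thickness),
    noise = substrate_uniform_noise(
      sub$E0 %||% stop_key("E0"), sub$amplitude %||% stop_key("amplitude"),
      geo$extent, geo$spacing, geo$nu, geo$thickness, seed = sub$seed),
    sinusoid = substrate_sinusoid(
      sub$E0 %||% stop_key("E0"), sub$amplitude %||% stop_key("amplitude"),
      sub$period %||% stop_key("period"), sub$axis %||% "x",
      geo$extent, geo$spacing, geo$nu, geo$thickness),
    gradient = substrate_linear_gradient(
      sub$E_min %||% 1, sub$slope %||% 20, geo$extent,
      geo$spacing, geo$nu, geo$thickness),
    stop("unknown substrate type: ", sub$type, call. = FALSE))

  grab <- function(block, ctor, extra = list()) {
    x <- raw[[block]] %||% list()
    check_keys(x, config_keys[[block]], block)
    for (nm in names(x))
      if (nm %in% c("T", "k_s", "k_c", "F_slip", "F_catch", "v0", "ell",
                    "t_fa", "dt", "gamma"))
        check_positive(x[[nm]], nm)
    do.call(ctor, utils::modifyList(extra, x))
  }
  cpmp <- grab("cpm", cpm_params)
  csp <- grab("catch_slip", catch_slip_params)
  bpp <- grab("buildup", buildup_params)
  cell <- raw$cell %||% list()
  check_keys(cell, config_keys$cell, "cell")
  tra <- raw$traction %||% list(); check_keys(tra, config_keys$traction, "traction")
  fbk <- raw$feedback %||% list(); check_keys(fbk, config_keys$feedback, "feedback")
  adh <- raw$adhesion %||% list(); check_keys(adh, config_keys$adhesion, "adhesion")
  N0 <- adh$N0 %||% 50
  sim_config(
    substrate = field,
    variant = as.character(raw$variant %||% "1"),
    n_mcs = raw$n_mcs %||% 2000,
    seed = raw$seed %||% 1,
    cell_radius = cell$radius %||% 28,
    cell_center = if (!is.null(cell$center)) as.numeric(cell$center),
    cpm = cpmp, cs = csp, bp = bpp,
    mu = tra$mu %||% 0.06,
    p = fbk$p %||% 2, sigma_h = fbk$sigma_h %||% 0.5,
    N0 = N0, N_seed = adh$N_seed %||% N0,
    N_total = adh$N_total %||% 2e5,
    snapshot_interval = raw$snapshot_interval %||% 0)
}

stop_key <- function(nm) stop("substrate block is missing `", nm, "`",
                              call. = FALSE)

config_to_list <- function(config) {
  sub <- config$substrate
  E <- sub$E
  type <- if (all(E == E[1])) "homogeneous"
          else if (all(abs(E - matrix(E[1, ], nrow(E), ncol(E), byrow = TRUE))
                       < 1e-9) &&
                   max(abs(diff(E[1, ], differences = 2))) < 1e-9) "gradient"
          else "raster"
  sub_list <- switch(type,
    homogeneous = list(type = "homogeneous", E0 = E[1]),
    gradient = list(type = "gradient",
                    E_min = E[1, 1] - 0.5 * diff(E[1, 1:2]),
                    slope = 1000 * diff(E[1, 1:2]) / sub$spacing),
    list(type = "homogeneous", E0 = mean(E)))  # rasters are not round-trippable
  sub_list <- c(sub_list, list(extent = sub$extent, spacing = sub$spacing,
                               nu = sub$nu, thickness = sub$thickness))
  list(variant = config$variant, n_mcs = config$n_mcs, seed = config$seed,
       substrate = sub_list,
       cell = list(radius = config$cell_radius,
                   center = as.numeric(config$cell_center)),
       cpm = Filter(Negate(is.null), unclass(config$cpm)),
       catch_slip = unclass(config$cs),
       buildup = unclass(config$bp),
       traction = list(mu = config$mu),
       feedback = list(p = config$p, sigma_h = config$sigma_h),
       adhesion = list(N0 = config$N0, N_seed = config$N_seed,
                       N_total = config$N_total),
       snapshot_interval = config$snapshot_interval)
}

#' Experiment presets
#'
#' Named study setups bundling a base configuration with the swept
#' parameter and replicate count:
#' \describe{
#'   \item{`spreading`}{model 1 on homogeneous substrates of 1, 5 and
#'     50 kPa, 2000 MCS: stiffness-dependent cell spreading.}
#'   \item{`elongation`}{model 2.1 across a stiffness series from soft to
#'     effectively rigid, 2000 MCS: biphasic cell elongation.}
#'   \item{`motor_velocity`}{model 2.1 with myosin motor velocity 10,
#'     100 and 1000 nm/s: the stiffness regime of elongation shifts with
#'     contraction rate.}
#'   \item{`durotaxis`}{a 20 Pa/um linear stiffness gradient (1 kPa at
#'     the left edge), cell starting mid-domain at 6 kPa, 10,000 MCS.}
#' }
#'
#' @param name preset name.
#' @return list with `name`, `base` (a [sim_config()]), `n_rep`, and
#'   optionally `sweep` (list with `param`, `values`).
#' @export
preset <- function(name) {
  known <- preset_names()
  if (!name %in% known)
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  switch(name,
    spreading = list(
      name = name,
      base = sim_config(substrate_homogeneous(50), variant = "1",
                        n_mcs = 2000),
      sweep = list(param = "substrate.E0", values = c(1, 5, 50)),
      n_rep = 25),
    elongation = list(
      name = name,
      base = sim_config(substrate_homogeneous(50), variant = "2.1",
                        n_mcs = 2000),
      sweep = list(param = "substrate.E0", values = c(1, 20, 50, 100, 5e4)),
      n_rep = 25),
    motor_velocity = list(
      name = name,
      base = sim_config(substrate_homogeneous(50), variant = "2.1",
                        n_mcs = 2000),
      sweep = list(param = "buildup.v0", values = c(0.01, 0.1, 1)),
      n_rep = 25),
    durotaxis = list(
      name = name,
      base = sim_config(substrate_linear_gradient(E_min = 1, slope = 20,
                                                  extent = 500),
                        variant = "2.1", n_mcs = 10000,
                        cell_center = c(250, 250)),
      sweep = NULL,
      n_rep = 25))
}

#' @rdname preset
#' @export
preset_names <- function() c("spreading", "elongation", "motor_velocity",
                             "durotaxis")

#' Expand a preset (or sweep) into per-run configurations
#'
#' Each run gets a deterministic seed `base_seed + run_index - 1`, with
#' replicates nested inside sweep values.
#'
#' @param pre a [preset()] result, or a list with `base` and optional
#'   `sweep`/`n_rep` entries.
#' @param n_rep replicate count override.
#' @param base_seed first seed.
#' @return list of [sim_config()] objects with `$label` attributes.
#' @export
expand_runs <- function(pre, n_rep = NULL, base_seed = 1) {
  n_rep <- n_rep %||% pre$n_rep %||% 1
  values <- if (is.null(pre$sweep)) list(NULL) else as.list(pre$sweep$values)
  runs <- list()
  k <- 0L
  for (v in values) {
    for (r in seq_len(n_rep)) {
      cfg <- pre$base
      if (!is.null(v)) cfg <- set_config_param(cfg, pre$sweep$param, v)
      k <- k + 1L
      cfg$seed <- as.integer(base_seed + k - 1L)
      attr(cfg, "label") <- if (is.null(v)) sprintf("rep%02d", r)
                            else sprintf("%s=%g_rep%02d", pre$sweep$param, v, r)
      runs[[k]] <- cfg
    }
  }
  runs
}

# dotted-path parameter override on a sim_config
set_config_param <- function(cfg, param, value) {
  parts <- strsplit(param, ".", fixed = TRUE)[[1]]
  if (parts[1] == "substrate" && parts[2] == "E0") {
    sub <- cfg$substrate
    cfg$substrate <- substrate_homogeneous(value, sub$extent, sub$spacing,
                                           sub$nu, sub$thickness)
  } else if (parts[1] == "substrate" && parts[2] == "slope") {
    sub <- cfg$substrate
    cfg$substrate <- substrate_linear_gradient(sub$E[1, 1], value, sub$extent,
                                               sub$spacing, sub$nu,
                                               sub$thickness)
  } else if (length(parts) == 2 && parts[1] %in% c("cpm", "cs", "bp")) {
    cfg[[parts[1]]][[parts[2]]] <- value
  } else if (length(parts) == 2 && parts[1] == "buildup") {
    cfg$bp[[parts[2]]] <- value
  } else if (length(parts) == 1 && parts[1] %in% names(cfg)) {
    cfg[[parts[1]]] <- value
  } else {
    stop("cannot set parameter path: ", param, call. = FALSE)
  }
  cfg
}
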