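#' Substrate stiffness fields
#'
#' Constructors for the per-site Young's modulus map of the elastic
#' substrate a simulated cell adheres to. All generators share a regular
#' grid of square sites: `extent` (um) divided by `spacing` (um) must be a
#' whole number of sites per axis. Stiffness is stored in kPa; a small
#' positive floor (0.01 kPa) guards against non-physical moduli when noise
#' is applied.
#'
#' @param E0 baseline Young's modulus (kPa).
#' @param extent domain size in um; a single number for a square domain or
#'   `c(width, height)`.
#' @param spacing lattice spacing in um (default 2.5, giving a 200x200 grid
#'   for the default 500 um domain).
#' @param nu substrate Poisson ratio (default 0.45, a nearly
#'   incompressible gel).
#' @param thickness substrate thickness in um (default 10); enters only as
#'   the load-to-stress scaling in the plane-stress solver.
#' @return A `stiffness_field`: list with `E` (ny x nx matrix, kPa), `nu`,
#'   `thickness`, `spacing`, `extent`, `nx`, `ny`.
#' @examples
#' f <- substrate_homogeneous(50)
#' dim(f$E)
#' @name substrate
NULL

new_stiffness_field <- function(E, nu, thickness, spacing, extent) {
  stopifnot(all(E > 0), nu >= 0, nu < 0.5, thickness > 0, spacing > 0)
  structure(
    list(E = E, nu = nu, thickness = thickness, spacing = spacing,
         extent = extent, nx = ncol(E), ny = nrow(E)),
    class = "stiffness_field")
}

field_grid_dims <- function(extent, spacing) {
  extent <- rep(as.numeric(extent), length.out = 2L)
  if (any(extent <= 0) || spacing <= 0)
    stop("extent and spacing must be positive", call. = FALSE)
  n <- extent / spacing
  if (any(abs(n - round(n)) > 1e-8))
    stop("extent must be an integer multiple of spacing", call. = FALSE)
  list(nx = as.integer(round(n[1])), ny = as.integer(round(n[2])),
       extent = extent)
}

#' @rdname substrate
#' @export
substrate_homogeneous <- function(E0, extent = 500, spacing = 2.5,
                                  nu = 0.45, thickness = 10) {
  if (E0 <= 0) stop("E0 must be positive", call. = FALSE)
  g <- field_grid_dims(extent, spacing)
  new_stiffness_field(matrix(E0, g$ny, g$nx), nu, thickness, spacing, g$extent)
}

#' @rdname substrate
#' @param amplitude noise (or sinusoid) amplitude in kPa.
#' @param seed integer seed making the noise field reproducible;
#'   `NULL` uses the current RNG state.
#' @details `substrate_uniform_noise()` draws every site independently from
#'   Uniform(E0 - amplitude, E0 + amplitude), clamped below at 0.01 kPa.
#' @export
substrate_uniform_noise <- function(E0, amplitude, extent = 500, spacing = 2.5,
                                    nu = 0.45, thickness = 10, seed = NULL) {
  if (E0 <= 0) stop("E0 must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  g <- field_grid_dims(extent, spacing)
  draw <- function() {
    E <- matrix(stats::runif(g$nx * g$ny, E0 - amplitude, E0 + amplitude),
                g$ny, g$nx)
    if (amplitude >= E0 && any(E < 0.01))
      message("noise amplitude reaches non-positive moduli; clamping at 0.01 kPa")
    pmax(E, 0.01)
  }
  E <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  new_stiffness_field(E, nu, thickness, spacing, g$extent)
}

#' @rdname substrate
#' @param period sinusoid period in um.
#' @param axis axis along which the sinusoid varies, `"x"` or `"y"`.
#' @details `substrate_sinusoid()` builds
#'   `E = E0 + amplitude * sin(2*pi*x/period)` along the chosen axis,
#'   evaluated at site centers.
#' @export
substrate_sinusoid <- function(E0, amplitude, period, axis = c("x", "y"),
                               extent = 500, spacing = 2.5,
                               nu = 0.45, thickness = 10) {
  axis <- match.arg(axis)
  if (E0 <= 0) stop("E0 must be positive", call. = FALSE)
  if (period <= 0) stop("period must be positive", call. = FALSE)
  if (amplitude < 0 || amplitude >= E0)
    stop("amplitude must satisfy 0 <= amplitude < E0", call. = FALSE)
  g <- field_grid_dims(extent, spacing)
  centers_x <- (seq_len(g$nx) - 0.5) * spacing
  centers_y <- (seq_len(g$ny) - 0.5) * spacing
  E <- if (axis == "x") {
    matrix(E0 + amplitude * sin(2 * pi * centers_x / period),
           g$ny, g$nx, byrow = TRUE)
  } else {
    matrix(E0 + amplitude * sin(2 * pi * centers_y / period), g$ny, g$nx)
  }
  new_stiffness_field(pmax(E, 0.01), nu, thickness, spacing, g$extent)
}

#' @rdname substrate
#' @param E_min stiffness at the left (x = 0) edge, kPa.
#' @param slope stiffness slope in Pa/um (1 kPa per 50 um at slope 20).
#' @details `substrate_linear_gradient()` builds `E(x) = E_min + slope*x`
#'   with `x` the site-center coordinate; the field is defined on the
#'   domain only (no extrapolation past the edges). The default 20 Pa/um
#'   gradient over a 500 um domain runs from 1 kPa on the left towards
#'   stiffer substrate on the right, with 6 kPa at x = 250 um.
#' @export
substrate_linear_gradient <- function(E_min = 1, slope = 20, extent = 500,
                                      spacing = 2.5, nu = 0.45, thickness = 10) {
  if (E_min <= 0) stop("E_min must be positive", call. = FALSE)
  if (slope < 0) stop("slope must be non-negative", call. = FALSE)
  g <- field_grid_dims(extent, spacing)
  centers_x <- (seq_len(g$nx) - 0.5) * spacing
  E <- matrix(E_min + (slope / 1000) * centers_x, g$ny, g$nx, byrow = TRUE)
  new_stiffness_field(E, nu, thickness, spacing, g$extent)
}

#' Query a stiffness field at a physical position
#'
#' @param field a `stiffness_field`.
#' @param x,y coordinates in um (vectorized).
#' @return Young's modulus (kPa) of the site containing each point.
#' @export
field_at <- function(field, x, y) {
  stopifnot(inherits(field, "stiffness_field"))
  ix <- pmin(pmax(ceiling(x / field$spacing), 1L), field$nx)
  iy <- pmin(pmax(ceiling(y / field$spacing), 1L), field$ny)
  field$E[cbind(iy, ix)]
}

#' Write a stiffness field as a CSV grid
#'
#' One row per lattice row, columns ordered by x; values in kPa.
#'
#' @param field a `stiffness_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "stiffness_field"))
  utils::write.table(field$E, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.stiffness_field <- function(x, ...) {
  cat(sprintf(
    "<stiffness_field> %d x %d sites (%.1f x %.1f um, dx = %g um)\n",
    x$nx, x$ny, x$extent[1], x$extent[2], x$spacing))
  cat(sprintf("  E: %.3g - %.3g kPa, nu = %g, thickness = %g um\n",
              min(x$E), max(x$E), x$nu, x$thickness))
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
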