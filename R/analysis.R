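#' Cell eccentricity from image moments
#'
#' Semi-axes of the equivalent ellipse are proportional to the square
#' roots of the eigenvalues of the central second-moment matrix of the
#' occupied site centers; only their ratio enters the eccentricity
#' `e = sqrt(1 - (b/a)^2)`, which is 0 for a circle and approaches 1 for
#' a line. A single-site cell returns 0 by convention.
#'
#' @param spin integer lattice matrix (0/1).
#' @param spacing lattice spacing (um).
#' @return eccentricity in `[0, 1]`.
#' @export
eccentricity <- function(spin, spacing = 2.5) {
  occ <- which(spin == 1L)
  if (length(occ) == 0) stop("cell is empty", call. = FALSE)
  if (length(occ) == 1) return(0)
  xy <- site_centers(occ, nrow(spin), spacing)
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Error-function fit of spreading kinetics
#'
#' Fits `A(t) = A50 * (1 + erf((t - t50) / tau))` to an area time course
#' by nonlinear least squares; `t50` is the time at which the cell
#' reaches half its maximal area.
#'
#' @param time time points (any consistent unit).
#' @param area areas (um^2).
#' @return list with estimates `A50`, `t50`, `tau`, their standard
#'   errors, 95 percent confidence intervals (`ci`, rows per parameter),
#'   the `fitted` curve, and `ok` (FALSE when the fit failed or is
#'   non-identifiable, e.g. a constant series).
#' @export
fit_spreading_erf <- function(time, area) {
  stopifnot(length(time) == length(area), length(time) >= 4)
  if (stats::sd(area) < 1e-12 * max(abs(area), 1))
    return(list(ok = FALSE, reason = "constant area series"))
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  a50_0 <- max(area) / 2
  t50_0 <- time[which.min(abs(area - a50_0))]
  tau_0 <- max(diff(range(time)) / 5, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      area ~ A50 * (1 + erf((time - t50) / tau)),
      start = list(A50 = a50_0, t50 = t50_0, tau = tau_0),
      lower = c(0, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE, reason = "fit did not converge"))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  list(ok = TRUE, A50 = est[["A50"]], t50 = est[["t50"]], tau = est[["tau"]],
       se = se, ci = ci, fitted = stats::fitted(fit))
}

#' Inverse-exponential fit of spreading kinetics
#'
#' Fits `A(t) = A0 + (Af - A0) * (1 - exp(-t/tau))` and also returns the
#' smoothed area growth rate dA/dt from central finite differences of a
#' running-mean-filtered series.
#'
#' @inheritParams fit_spreading_erf
#' @param smooth_k running-mean window (odd number of samples) for dA/dt.
#' @return list with `A0`, `Af`, `tau`, `se`, `ci`, `fitted`, `dAdt`
#'   (same length as input), and `ok`.
#' @export
fit_spreading_exp <- function(time, area, smooth_k = 11) {
  stopifnot(length(time) == length(area), length(time) >= 4)
  if (stats::sd(area) < 1e-12 * max(abs(area), 1))
    return(list(ok = FALSE, reason = "constant area series"))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      area ~ A0 + (Af - A0) * (1 - exp(-time / tau)),
      start = list(A0 = area[1], Af = max(area),
                   tau = max(diff(range(time)) / 5, 1e-9)),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE, reason = "fit did not converge"))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  k <- min(smooth_k, length(area) - (1 - length(area) %% 2))
  if (k %% 2 == 0) k <- k - 1
  sm <- if (k >= 3) stats::filter(area, rep(1 / k, k), sides = 2) else area
  sm <- as.numeric(sm)
  nas <- is.na(sm); sm[nas] <- area[nas]
  dAdt <- c(NA, diff(sm, lag = 2) / diff(time, lag = 2), NA)
  list(ok = TRUE, A0 = est[["A0"]], Af = est[["Af"]], tau = est[["tau"]],
       se = se, ci = cbind(lower = est - 1.96 * se, upper = est + 1.96 * se),
       fitted = stats::fitted(fit), dAdt = dAdt)
}

#' Summary statistics of pooled adhesion cluster sizes
#'
#' @param N vector of cluster bond counts (pooled over replicates).
#' @param threshold size threshold for the upper-tail fraction
#'   (default 100 bonds).
#' @return list with `median`, `sd`, `kurtosis` (Pearson convention,
#'   normal = 3), `frac_above` (fraction strictly above the threshold),
#'   and `n`.
#' @export
cluster_stats <- function(N, threshold = 100) {
  if (length(N) == 0)
    return(list(median = NA_real_, sd = NA_real_, kurtosis = NA_real_,
                frac_above = NA_real_, n = 0L, ok = FALSE))
  m <- mean(N)
  m2 <- mean((N - m)^2)
  kurt <- if (m2 > 0) mean((N - m)^4) / m2^2 else NA_real_
  list(median = stats::median(N), sd = stats::sd(N), kurtosis = kurt,
       frac_above = mean(N > threshold), n = length(N), ok = TRUE)
}

#' Durotaxis velocity from centroid trajectories
#'
#' Ordinary least-squares slope of centroid x versus time per replicate,
#' with the ensemble mean and standard deviation. When trajectories from
#' several conditions are supplied, one-way ANOVA and pairwise Welch
#' t tests compare the condition means.
#'
#' @param trajectories a list of data frames with columns `time_h` and
#'   `x` (um), or a single data frame.
#' @param condition optional factor, one level per trajectory, for
#'   cross-condition tests.
#' @return list with `slopes` (um/h per trajectory), `mean`, `sd`, and,
#'   when `condition` is given, `anova` and `pairwise` test results.
#' @export
durotaxis_speed <- function(trajectories, condition = NULL) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  slopes <- vapply(trajectories, function(tr) {
    stopifnot(nrow(tr) >= 2)
    unname(stats::coef(stats::lm(x ~ time_h, data = tr))[2])
  }, numeric(1))
  out <- list(slopes = slopes, mean = mean(slopes), sd = stats::sd(slopes))
  if (!is.null(condition)) {
    condition <- factor(condition)
    stopifnot(length(condition) == length(slopes))
    df <- data.frame(slope = slopes, condition = condition)
    out$anova <- stats::aov(slope ~ condition, data = df)
    out$pairwise <- stats::pairwise.t.test(df$slope, df$condition,
                                           pool.sd = FALSE)
  }
  out
}

#' Extract a centroid trajectory from run morphometrics
#'
#' @param result a `sim_result`.
#' @return data frame with `time_h` and `x` (um), ready for
#'   [durotaxis_speed()].
#' @export
trajectory_of <- function(result) {
  m <- result$morphometrics
  data.frame(time_h = m$time_s / 3600, x = m$centroid_x)
}
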