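#' Cumulative exhaustion clock along a tumour trajectory
#'
#' Precomputes the two cumulative integrals that drive the characteristics
#' solution of the continuum model: K(t) = integral of (kappa0 + kappa1 N(u))
#' du (the exhaustion clock) and the plain integral of N(u) du. Both are
#' accumulated by the trapezoidal rule on the trajectory's output grid, so
#' the trajectory should be stored densely (>= 1e4 points is used throughout
#' the package for PDE work).
#'
#' @param traj an `exhaustion_trajectory` from [simulate_reduced()].
#' @param params a [dimensionless_parameters()] object; defaults to the
#'   trajectory's own parameters.
#' @return An object of class `"exhaustion_clock"`: a list with `time`,
#'   `K` (cumulative exhaustion integral), `intN` (cumulative integral of N),
#'   `N` (the tumour path) and `params`.
#' @export
build_clock <- function(traj, params = NULL) {
  stopifnot(inherits(traj, "exhaustion_trajectory"))
  if (is.null(params)) params <- attr(traj, "params")
  tt <- traj$time
  if (any(diff(tt) <= 0)) stop("trajectory time grid must be increasing",
                               call. = FALSE)
  N <- traj$N
  cumtrap <- function(y) c(0, cumsum(diff(tt) * (y[-1] + y[-length(y)]) / 2))
  kvals <- params$kappa0 + params$kappa1 * N
  structure(list(time = tt, K = cumtrap(kvals), intN = cumtrap(N), N = N,
                 params = params),
            class = "exhaustion_clock")
}

clock_interp <- function(clock, what, t) {
  stats::approx(clock$time, clock[[what]], xout = t, rule = 2)$y
}

#' Exhaustion wavefront S(t)
#'
#' The characteristic emanating from (s, t) = (0, 0): S(t) = 1 - exp(-K(t)).
#' It separates T-cells resident at t = 0 (region A, ahead of the front) from
#' T-cells recruited afterwards (region B, behind it), is strictly increasing
#' and tends to 1 as t grows.
#'
#' @param clock an [build_clock()] object.
#' @param t evaluation times (default: the clock's grid).
#' @return S(t), vectorised.
#' @export
wavefront <- function(clock, t = clock$time) {
  1 - exp(-clock_interp(clock, "K", t))
}

#' Resident-cell (region A) density
#'
#' Ahead of the wavefront the density follows the initial profile advected
#' and amplified along characteristics:
#' T(s, t) = (1/kappa0) (1 - s)^-(1 - gamma_t/kappa0) *
#' exp((gamma_t kappa1 / kappa0) * integral of N). At t = 0 it reduces to the
#' tumour-free initial profile; for a tumour settling at
#' N* < (gamma_t - kappa0)/kappa1 it decays to zero.
#'
#' @param s exhaustion level(s) with S(t) < s <= 1 - 1e-3.
#' @param t a single evaluation time.
#' @param clock an [build_clock()] object.
#' @param params defaults to the clock's parameters.
#' @return T(s, t), vectorised over `s`.
#' @export
region_A_density <- function(s, t, clock, params = clock$params) {
  S <- wavefront(clock, t)
  if (any(s <= S)) stop("region A requires s > S(t)", call. = FALSE)
  k0 <- params$kappa0; gt <- params$gamma_t
  (1 / k0) * (1 - s)^(-(1 - gt / k0)) *
    exp(gt * params$kappa1 / k0 * clock_interp(clock, "intN", t))
}

#' Infiltration time of a recruited T-cell
#'
#' For a point (s, t) behind the wavefront, solves K(t) - K(t0) = -log(1 - s)
#' for the time t0 at which a T-cell now at exhaustion level s entered the
#' tumour microenvironment. The clock is strictly increasing, so the
#' inversion is a monotone interpolation; t0(0, t) = t.
#'
#' @param s exhaustion level(s) with 0 <= s < S(t).
#' @param t a single evaluation time.
#' @param clock an [build_clock()] object.
#' @return t0 in [0, t], vectorised over `s`.
#' @export
infiltration_time <- function(s, t, clock) {
  S <- wavefront(clock, t)
  if (any(s >= S)) stop("region B requires s < S(t)", call. = FALSE)
  Kt <- clock_interp(clock, "K", t)
  target <- Kt + log(1 - s)          # K(t0); log(1-s) <= 0
  t0 <- stats::approx(clock$K, clock$time, xout = target, rule = 2)$y
  pmin(pmax(t0, 0), t)
}

#' Recruited-cell (region B) density
#'
#' Behind the wavefront the density is set by the boundary influx at the
#' infiltration time t0(s, t):
#' T(s, t) = exp(-gamma_t (t - t0)) * sigma(N(t0)) /
#' ((kappa0 + kappa1 N(t0)) (1 - s)). At s = 0 it reduces to the boundary
#' condition, and it grows like 1/(1 - s) towards the fully exhausted end.
#'
#' @inheritParams infiltration_time
#' @param params defaults to the clock's parameters.
#' @return T(s, t), vectorised over `s`.
#' @export
region_B_density <- function(s, t, clock, params = clock$params) {
  t0 <- infiltration_time(s, t, clock)
  N0 <- clock_interp(clock, "N", t0)
  exp(-params$gamma_t * (t - t0)) * influx_rate(N0, params) /
    (exhaustion_rate(N0, params) * (1 - s))
}

#' Evaluate the continuum exhaustion density T(s, t)
#'
#' Dispatches every (s, t) pair to the resident-cell (region A) or
#' recruited-cell (region B) analytic branch by comparing s with the
#' wavefront S(t), and records the region tag and front position. Evaluation
#' is capped at s = 1 - 1e-3 because the recruited branch carries a
#' 1/(1 - s) singularity at the fully exhausted end.
#'
#' @param s_grid exhaustion levels in [0, 1 - 1e-3].
#' @param t_points evaluation times (dimensionless).
#' @param params a [dimensionless_parameters()] object.
#' @param traj optional dense reduced trajectory covering `max(t_points)`;
#'   simulated on a 1e4-point grid when omitted.
#' @return A `pde_density` object: a list with `s`, `t`, `values` (matrix,
#'   s by t), `region` (character matrix "A"/"B"), `wavefront` (S at each t)
#'   and `clock`.
#' @export
evaluate_density <- function(s_grid, t_points, params, traj = NULL) {
  stopifnot(all(s_grid >= 0), all(s_grid <= 1 - 1e-3 + 1e-12))
  if (is.null(traj))
    traj <- simulate_reduced(params, max(t_points) * 1.0001, n_out = 10001)
  clock <- build_clock(traj, params)
  vals <- matrix(NA_real_, length(s_grid), length(t_points))
  reg <- matrix(NA_character_, length(s_grid), length(t_points))
  S <- wavefront(clock, t_points)
  for (j in seq_along(t_points)) {
    behind <- s_grid < S[j]
    reg[, j] <- ifelse(behind, "B", "A")
    if (any(behind))
      vals[behind, j] <- region_B_density(s_grid[behind], t_points[j], clock)
    if (any(!behind))
      vals[!behind, j] <- region_A_density(s_grid[!behind], t_points[j], clock)
  }
  structure(list(s = s_grid, t = t_points, values = vals, region = reg,
                 wavefront = S, clock = clock, params = params),
            class = "pde_density")
}

#' Explicit density for a constant exhaustion rate
#'
#' When kappa1 = 0 the exhaustion clock is linear and the characteristics
#' solution collapses to a two-branch closed form: behind the front
#' (s < 1 - exp(-kappa0 t)) the density is the boundary influx evaluated at
#' the shifted time t + log(1 - s)/kappa0 times the initial-profile shape;
#' ahead of it, the stationary initial profile. The branch boundary is a
#' genuine discontinuity and both one-sided limits are returned by evaluating
#' each branch.
#'
#' @param s exhaustion level(s) in [0, 1).
#' @param t a single evaluation time.
#' @param params a [dimensionless_parameters()] object with `kappa1 = 0`
#'   (an error otherwise).
#' @param traj a reduced trajectory supplying N(t) (simulated if omitted).
#' @return T(s, t), vectorised over `s`.
#' @export
explicit_constant_rate_density <- function(s, t, params, traj = NULL) {
  if (params$kappa1 != 0)
    stop("closed form requires kappa1 = 0", call. = FALSE)
  if (is.null(traj)) traj <- simulate_reduced(params, t * 1.0001, n_out = 10001)
  k0 <- params$kappa0; gt <- params$gamma_t
  front <- 1 - exp(-k0 * t)
  shape <- (1 - s)^(-(1 - gt / k0))
  out <- shape / k0
  behind <- s < front
  if (any(behind)) {
    tshift <- t + log(1 - s[behind]) / k0
    Ns <- stats::approx(traj$time, traj$N, xout = tshift, rule = 2)$y
    out[behind] <- shape[behind] / k0 * influx_rate(Ns, params)
  }
  out
}

#' Convergence of the compartment model to the continuum limit
#'
#' For each compartment count n, simulates the structured model, rescales the
#' compartment masses to densities (n * T_j at s = j/n), and measures the L1
#' discrepancy against the analytic characteristics solution on s in
#' [0, s_max], excluding a band of half-width 2/n around the wavefront where
#' the discrete front is smeared. The discrepancy decreases as n grows (the
#' continuum model is the leading-order limit in 1/n).
#'
#' @param params a [dimensionless_parameters()] object.
#' @param t_eval evaluation time (dimensionless).
#' @param n_values compartment counts to compare, e.g. `c(10, 100, 1000)`.
#' @param s_max upper end of the comparison window (default 0.9, away from
#'   the 1/(1 - s) singularity).
#' @return A data frame with columns `n`, `l1_error`, `n_points`.
#' @export
compare_with_discrete <- function(params, t_eval, n_values = c(10, 100, 1000),
                                  s_max = 0.9) {
  traj <- simulate_reduced(params, t_eval * 1.0001, n_out = 10001)
  clock <- build_clock(traj, params)
  S <- wavefront(clock, t_eval)
  rows <- lapply(n_values, function(n) {
    q <- params; q$n <- as.integer(n)
    dtraj <- simulate_discrete(q, t_eval, n_out = 101)
    final <- unlist(dtraj[nrow(dtraj), grep("^T[0-9]+$", names(dtraj))])
    s <- (0:n) / n
    keep <- s <= s_max & abs(s - S) > 2 / n
    dens_disc <- n * final[keep]
    dens_pde <- vapply(s[keep], function(si) {
      if (si < S) region_B_density(si, t_eval, clock)
      else region_A_density(si, t_eval, clock)
    }, numeric(1))
    data.frame(n = n, l1_error = mean(abs(dens_disc - dens_pde)),
               n_points = sum(keep))
  })
  do.call(rbind, rows)
}

#' @export
print.pde_density <- function(x, ...) {
  cat(sprintf(
    "Continuum exhaustion density: %d s-points x %d times; S(t) = %s\n",
    length(x$s), length(x$t),
    paste(signif(x$wavefront, 4), collapse = ", ")))
  invisible(x)
}

#' @export
plot.pde_density <- function(x, ...) {
  graphics::matplot(x$s, x$values, type = "l", lty = 1,
                    xlab = "exhaustion level s", ylab = "T(s, t)", ...)
  graphics::abline(v = x$wavefront, lty = 3, col = "grey50")
  invisible(x)
}
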