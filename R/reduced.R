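#' Dimensionless T-cell influx and exhaustion rates
#'
#' `influx_rate()` is the biphasic recruitment rate sigma(N) = 1 +
#' sigma_t * N / (1 + (N/N_t)^2): it grows roughly linearly for small tumours,
#' peaks at N = N_t with value 1 + sigma_t*N_t/2, and decays back towards the
#' basal rate 1 as large tumours shut out infiltrating T-cells.
#' `exhaustion_rate()` is the linear antigen-load-driven rate
#' k(N) = kappa0 + kappa1 * N.
#'
#' @param N tumour burden (vectorised, fraction of carrying capacity).
#' @param params a [dimensionless_parameters()] object.
#' @return Numeric vector of rates.
#' @export
influx_rate <- function(N, params) {
  1 + params$sigma_t * N / (1 + (N / params$N_t)^2)
}

#' @rdname influx_rate
#' @export
exhaustion_rate <- function(N, params) {
  params$kappa0 + params$kappa1 * N
}

# analytic derivatives used by the stability formulas
influx_rate_deriv <- function(N, params) {
  u <- (N / params$N_t)^2
  params$sigma_t * (1 - u) / (1 + u)^2
}

#' Treatment schedule acting on the exhaustion rate
#'
#' A single course of a therapy (e.g. checkpoint blockade) that transiently
#' lowers the tumour-enhanced exhaustion rate kappa1 by `delta_kappa`,
#' following a trapezoid in time: constant at baseline until `t_on` days, a
#' linear ramp down over `ramp` days, a plateau of `plateau` days at
#' kappa1 - delta_kappa, and a symmetric linear ramp back.
#'
#' @param t_on treatment start (days). Default 100.
#' @param ramp ramp duration (days). Default 25.
#' @param plateau plateau duration (days). Default 50.
#' @param delta_kappa reduction in kappa1 during the plateau. Default 1.2.
#' @return An object of class `"treatment_schedule"`.
#' @export
treatment_schedule <- function(t_on = 100, ramp = 25, plateau = 50,
                               delta_kappa = 1.2) {
  stopifnot(t_on >= 0, ramp >= 0, plateau >= 0)
  structure(list(t_on = t_on, ramp = ramp, plateau = plateau,
                 delta_kappa = delta_kappa),
            class = "treatment_schedule")
}

#' Time-dependent exhaustion-rate parameter kappa1(t)
#'
#' Evaluates the trapezoid treatment profile at a time in days. With no
#' schedule the baseline is returned unchanged. If the schedule would drive
#' kappa1 to zero or below, a warning is issued (once per call).
#'
#' @param t_days time in days (vectorised).
#' @param base baseline kappa1.
#' @param sched a [treatment_schedule()] or `NULL`.
#' @return kappa1 at each requested time.
#' @export
kappa1_at_time <- function(t_days, base, sched = NULL) {
  if (is.null(sched)) return(rep_len(base, length(t_days)))
  stopifnot(inherits(sched, "treatment_schedule"))
  if (base - sched$delta_kappa <= 0)
    warning("treatment drives kappa1 to a non-positive value at the plateau")
  t1 <- sched$t_on
  t2 <- t1 + sched$ramp
  t3 <- t2 + sched$plateau
  t4 <- t3 + sched$ramp
  drop_frac <- numeric(length(t_days))
  if (sched$ramp > 0) {
    on_ramp_down <- t_days >= t1 & t_days < t2
    on_ramp_up <- t_days >= t3 & t_days < t4
    drop_frac[on_ramp_down] <- (t_days[on_ramp_down] - t1) / sched$ramp
    drop_frac[on_ramp_up] <- (t4 - t_days[on_ramp_up]) / sched$ramp
    drop_frac[t_days >= t2 & t_days < t3] <- 1
  } else {
    drop_frac[t_days >= t1 & t_days < t4] <- 1
  }
  base - sched$delta_kappa * drop_frac
}

# kappa1 at dimensionless time t (schedule breakpoints live in days)
kappa1_at_dimensionless_time <- function(t, params, sched = NULL) {
  if (is.null(sched)) return(params$kappa1)
  kappa1_at_time(t / growth_rate(params), params$kappa1, sched)
}

#' Right-hand side of the reduced three-variable model
#'
#' Rates of change of (Theta, mu, N): T-cell influx minus death for the total,
#' exhaustion drift minus dilution by fresh (fully active) recruits for the
#' mean, and logistic growth minus exhaustion-weighted T-cell kill for the
#' tumour, i.e. dN/dt = N(1-N) - lam_t * N * Theta * (1 - mu).
#'
#' @param state numeric vector `c(Theta, mu, N)` or a named list.
#' @param params a [dimensionless_parameters()] object.
#' @param sched optional [treatment_schedule()].
#' @param t dimensionless time (only needed when `sched` is given). Default 0.
#' @return Numeric vector `c(dTheta, dmu, dN)`.
#' @export
reduced_rhs <- function(state, params, sched = NULL, t = 0) {
  state <- unlist(state, use.names = FALSE)[1:3]
  Theta <- state[1]; mu <- state[2]; N <- state[3]
  if (Theta <= 0) stop("Theta must be positive (the mu equation divides by it)",
                       call. = FALSE)
  k1t <- kappa1_at_dimensionless_time(t, params, sched)
  sig <- influx_rate(N, params)
  kN <- params$kappa0 + k1t * N
  c(Theta = sig - params$gamma_t * Theta,
    mu    = kN * (1 - mu) - mu * sig / Theta,
    N     = N * (1 - N) - params$lam_t * N * Theta * (1 - mu))
}

#' Initial condition of the reduced model
#'
#' The T-cell population starts at its tumour-free steady state: Theta(0) =
#' 1/gamma_t and mu(0) = kappa0 / (kappa0 + gamma_t); the tumour starts at N0.
#'
#' @param params a [dimensionless_parameters()] object.
#' @return Named numeric vector `c(Theta, mu, N)`.
#' @export
initial_reduced_state <- function(params) {
  c(Theta = 1 / params$gamma_t,
    mu = params$kappa0 / (params$kappa0 + params$gamma_t),
    N = params$N0)
}

new_trajectory <- function(df, params, kind, sched = NULL) {
  structure(df, class = c("exhaustion_trajectory", "data.frame"),
            params = params, kind = kind, schedule = sched)
}

solver_defaults <- function(opts = list()) {
  utils::modifyList(list(method = "ode45", rtol = 1e-8, atol = 1e-10), opts)
}

#' Simulate the reduced model
#'
#' Integrates the three-variable system with an adaptive Runge-Kutta 4(5)
#' scheme (deSolve's `ode45`; relative tolerance 1e-8, absolute 1e-10) from
#' [initial_reduced_state()] (or a caller-supplied state) and returns the
#' solution on a uniform output grid.
#'
#' @param params a [dimensionless_parameters()] object.
#' @param t_end final dimensionless time (multiply days by the growth rate `r`
#'   to convert).
#' @param sched optional [treatment_schedule()] (breakpoints in days).
#' @param n_out number of output points (default 2001).
#' @param state0 optional initial state `c(Theta, mu, N)`.
#' @param solver_opts optional list overriding `method`, `rtol`, `atol`.
#' @return An `exhaustion_trajectory` data frame with columns
#'   `time, Theta, mu, N`.
#' @export
simulate_reduced <- function(params, t_end, sched = NULL, n_out = 2001,
                             state0 = NULL, solver_opts = list()) {
  stopifnot(t_end > 0)
  validate_dimensionless(params)
  if (is.null(state0)) state0 <- initial_reduced_state(params)
  names(state0) <- c("Theta", "mu", "N")
  so <- solver_defaults(solver_opts)
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) list(reduced_rhs(y, params, sched, t))
  sol <- deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                      method = so$method, rtol = so$rtol, atol = so$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("reduced-model integration failed; last state: ",
         paste(signif(sol[nrow(sol), ], 6), collapse = ", "), call. = FALSE)
  df <- as.data.frame(sol)
  check_reduced_invariants(df)
  new_trajectory(df, params, "reduced", sched)
}

check_reduced_invariants <- function(df, tol = 1e-9) {
  if (any(df$Theta <= 0))
    stop("invariant violation: Theta must stay positive", call. = FALSE)
  if (any(df$mu < -tol | df$mu > 1 + tol))
    stop("invariant violation: mu left [0, 1] beyond solver tolerance",
         call. = FALSE)
  if (any(df$N < -tol))
    stop("invariant violation: N became negative beyond solver tolerance",
         call. = FALSE)
  invisible(df)
}

#' Classify the long-term outcome of a trajectory
#'
#' Assigns one of the immunoediting outcomes: `"elimination"` when the final
#' tumour burden is below 1e-4 (about 5e4 cells at the default carrying
#' capacity), otherwise the outcome label of the nearest stable steady state
#' in N. If the trajectory has not yet settled (sup-norm of the right-hand
#' side above 1e-6 at the final time), integration is continued from the final
#' state for up to nine further multiples of the original horizon before
#' giving up and returning `"undecided"`.
#'
#' @param traj an `exhaustion_trajectory` from [simulate_reduced()] (compartment
#'   trajectories are first collapsed to their moments).
#' @param steadies optional data frame from [find_steady_states()]; computed
#'   from the trajectory's parameters when omitted.
#' @param elimination_threshold burden below which the tumour counts as
#'   eliminated. Default 1e-4.
#' @return A single string: `"elimination"`, `"equilibrium"`, `"escape"` or
#'   `"undecided"`.
#' @export
classify_outcome <- function(traj, steadies = NULL,
                             elimination_threshold = 1e-4) {
  stopifnot(inherits(traj, "exhaustion_trajectory"))
  params <- attr(traj, "params")
  sched <- attr(traj, "schedule")
  if (attr(traj, "kind") == "discrete") traj <- moments_trajectory(traj)
  if (is.null(steadies)) steadies <- find_steady_states(params)
  t_end <- traj$time[nrow(traj)]
  final <- unlist(traj[nrow(traj), c("Theta", "mu", "N")])
  # treatment: only the post-treatment (baseline-kappa1) attractors matter
  rhs_now <- function(st, t) reduced_rhs(st, params, sched, t)
  extra <- 0
  while (max(abs(rhs_now(final, t_end))) >= 1e-6 && extra < 9) {
    more <- simulate_reduced(params, traj$time[nrow(traj)] - traj$time[1] + 1e-9,
                             sched = NULL, n_out = 501, state0 = final)
    final <- unlist(more[nrow(more), c("Theta", "mu", "N")])
    t_end <- t_end + more$time[nrow(more)]
    extra <- extra + 1
  }
  if (max(abs(reduced_rhs(final, params))) >= 1e-6) return("undecided")
  if (final["N"] < elimination_threshold) return("elimination")
  st <- steadies[steadies$stable & steadies$N_star > 0, , drop = FALSE]
  if (nrow(st) == 0) return("undecided")
  st$outcome[which.min(abs(st$N_star - final["N"]))]
}

#' @export
print.exhaustion_trajectory <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("<%s trajectory: %d time points on [0, %.4g]%s>\n",
              kind, nrow(x), x$time[nrow(x)],
              if (!is.null(attr(x, "schedule"))) ", with treatment" else ""))
  print.data.frame(utils::head(as.data.frame(x), 4), ...)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.exhaustion_trajectory <- function(x, ...) {
  params <- attr(x, "params")
  r <- growth_rate(params)
  if (attr(x, "kind") == "discrete") x <- moments_trajectory(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time / r, x$N, type = "l", col = "red3",
                 xlab = "time (days)", ylab = "tumour burden N", ...)
  graphics::plot(x$time / r, x$Theta, type = "l", col = "blue3",
                 xlab = "time (days)", ylab = expression(Theta), ...)
  graphics::plot(x$time / r, x$mu, type = "l", col = "darkgreen",
                 xlab = "time (days)", ylab = expression(mu), ylim = c(0, 1),
                 ...)
  invisible(x)
}
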