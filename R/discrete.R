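#' Initial exhaustion distribution of the compartment model
#'
#' The T-cell compartments start at the tumour-free steady state of the
#' structured system: T0(0) = 1 / (kappa0 * n + gamma_t) and the downward
#' recursion T_j(0) = kappa0 (n - j + 1) / (gamma_t + kappa0 (n - j)) *
#' T_{j-1}(0). Its total equals 1/gamma_t and its first moment equals
#' kappa0 / (kappa0 + gamma_t), matching the reduced model's initial state.
#'
#' @param params a [dimensionless_parameters()] object (supplies `n` and `N0`).
#' @return Named numeric vector `c(T0, ..., Tn, N)`.
#' @export
initial_distribution <- function(params) {
  n <- params$n
  k0 <- params$kappa0; gt <- params$gamma_t
  T <- numeric(n + 1)
  T[1] <- 1 / (k0 * n + gt)
  for (j in seq_len(n))
    T[j + 1] <- k0 * (n - j + 1) / (gt + k0 * (n - j)) * T[j]
  stats::setNames(c(T, params$N0), c(paste0("T", 0:n), "N"))
}

#' Right-hand side of the exhaustion-compartment model
#'
#' Compartment fluxes: fully active cells (j = 0) receive the full influx
#' sigma(N) and lose cells to exhaustion at rate k(N) * n; interior
#' compartments exchange mass at rate k(N) * n * (1 - j/n), which vanishes at
#' j = n so the fully exhausted class only ever loses cells to death. The
#' tumour obeys dN/dt = N(1-N) - lam_t * N * sum_j (1 - j/n) T_j, the
#' exhaustion-weighted kill; this is identical to the reduced model's
#' Theta (1 - mu) term.
#'
#' @param state numeric vector `c(T0..Tn, N)`.
#' @param params a [dimensionless_parameters()] object.
#' @param sched optional [treatment_schedule()].
#' @param t dimensionless time (used only with a schedule). Default 0.
#' @return Vector of rates, same layout as `state`.
#' @export
discrete_rhs <- function(state, params, sched = NULL, t = 0) {
  n <- params$n
  state <- unlist(state, use.names = FALSE)
  stopifnot(length(state) == n + 2)
  T <- state[1:(n + 1)]; N <- state[n + 2]
  k1t <- kappa1_at_dimensionless_time(t, params, sched)
  kN <- params$kappa0 + k1t * N
  sig <- influx_rate(N, params)
  w <- 1 - (0:n) / n                      # per-compartment activity weights
  outflux <- kN * n * w * T               # zero for j = n by construction
  dT <- c(0, outflux[1:n]) - outflux - params$gamma_t * T
  dT[1] <- dT[1] + sig
  dN <- N * (1 - N) - params$lam_t * N * sum(w * T)
  c(dT, dN)
}

#' Simulate the exhaustion-compartment model
#'
#' Integrates the `n + 2` equations (compartments plus tumour) with the same
#' adaptive Runge-Kutta 4(5) settings as [simulate_reduced()], starting from
#' [initial_distribution()].
#'
#' @inheritParams simulate_reduced
#' @param state0 optional initial state `c(T0..Tn, N)`.
#' @return An `exhaustion_trajectory` data frame with columns
#'   `time, T0..Tn, N`.
#' @export
simulate_discrete <- function(params, t_end, sched = NULL, n_out = 2001,
                              state0 = NULL, solver_opts = list()) {
  stopifnot(t_end > 0)
  validate_dimensionless(params)
  if (is.null(state0)) state0 <- initial_distribution(params)
  so <- solver_defaults(solver_opts)
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) list(discrete_rhs(y, params, sched, t))
  sol <- deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                      method = so$method, rtol = so$rtol, atol = so$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("compartment-model integration failed; last state: ",
         paste(signif(sol[nrow(sol), ], 6), collapse = ", "), call. = FALSE)
  df <- as.data.frame(sol)
  tc <- grep("^T[0-9]+$", names(df))
  if (any(unlist(df[tc]) < -1e-9) || any(df$N < -1e-9))
    stop("invariant violation: negative compartment or tumour value beyond ",
         "solver tolerance", call. = FALSE)
  new_trajectory(df, params, "discrete", sched)
}

#' Moments of an exhaustion distribution
#'
#' Summarises a compartment state by its total (Theta), mean exhaustion level
#' (the first moment of j/n weighted by T_j / Theta) and the variance of j/n
#' under the same weights.
#'
#' @param state numeric vector of compartment masses `T0..Tn` (a trailing
#'   tumour entry named `"N"` is ignored if present).
#' @return A list with `levels` (the j/n grid), `masses`, `total`, `mean`,
#'   and `variance`.
#' @export
distribution_moments <- function(state) {
  x <- unlist(state)
  if (!is.null(names(x)) && "N" %in% names(x)) x <- x[names(x) != "N"]
  n <- length(x) - 1L
  if (n < 1) stop("need at least two compartments", call. = FALSE)
  total <- sum(x)
  if (total <= 0) stop("all-zero exhaustion distribution has no moments",
                       call. = FALSE)
  lev <- (0:n) / n
  m <- sum(lev * x) / total
  v <- sum((lev - m)^2 * x) / total
  list(levels = lev, masses = unname(x), total = total, mean = m, variance = v)
}

#' Collapse a compartment trajectory to its moment trajectory
#'
#' Computes, at every output time, the T-cell total Theta and mean exhaustion
#' level mu of a compartment trajectory, returning a reduced-style trajectory
#' `(time, Theta, mu, N)`. Because the moment reduction of the compartment
#' system is exact, this agrees with [simulate_reduced()] up to solver error.
#'
#' @param traj an `exhaustion_trajectory` from [simulate_discrete()].
#' @return A reduced-style `exhaustion_trajectory`.
#' @export
moments_of <- function(traj) moments_trajectory(traj)

# collapse a compartment trajectory to (Theta, mu, N) per output time
moments_trajectory <- function(traj) {
  stopifnot(attr(traj, "kind") == "discrete")
  tc <- grep("^T[0-9]+$", names(traj))
  n <- length(tc) - 1L
  lev <- (0:n) / n
  Tm <- as.matrix(traj[tc])
  Theta <- rowSums(Tm)
  mu <- as.vector(Tm %*% lev) / Theta
  new_trajectory(data.frame(time = traj$time, Theta = Theta, mu = mu,
                            N = traj$N),
                 attr(traj, "params"), "reduced", attr(traj, "schedule"))
}
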