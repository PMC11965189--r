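#' Construct a tumour-immune exhaustion model
#'
#' The central object of the package: a parameterised dynamical system
#' coupling a logistically growing tumour to a cytotoxic T-cell population
#' structured by exhaustion level. Accepts either a dimensional or a
#' dimensionless parameter set (dimensional sets are nondimensionalised on
#' construction) and an optional treatment schedule.
#'
#' @param params a [dimensional_parameters()] or [dimensionless_parameters()]
#'   object; defaults to the literature parameter set.
#' @param schedule optional [treatment_schedule()].
#' @param n number of exhaustion compartments when `params` is dimensional.
#' @return An object of class `"exhaustion_model"`.
#' @examples
#' m <- exhaustion_model()
#' summary(m)
#' traj <- simulate(m, t_end_days = 250)
#' classify_outcome(traj)
#' @export
exhaustion_model <- function(params = dimensionless_parameters(),
                             schedule = NULL, n = 10L) {
  dimensional <- NULL
  if (inherits(params, "dimensional_parameters")) {
    dimensional <- params
    params <- nondimensionalise(params, n = n)
  }
  stopifnot(inherits(params, "dimensionless_parameters"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "treatment_schedule"))
  structure(list(params = params, dimensional = dimensional,
                 schedule = schedule),
            class = "exhaustion_model")
}

#' @export
print.exhaustion_model <- function(x, ...) {
  cat("Tumour-immune model with exhaustion-structured T-cells\n")
  print(x$params)
  if (!is.null(x$schedule))
    cat(sprintf(paste0("Treatment: kappa1 reduced by %.3g from day %g ",
                       "(ramp %g d, plateau %g d)\n"),
                x$schedule$delta_kappa, x$schedule$t_on, x$schedule$ramp,
                x$schedule$plateau))
  invisible(x)
}

#' @export
coef.exhaustion_model <- function(object, ...) {
  p <- object$params
  c(lam_t = p$lam_t, sigma_t = p$sigma_t, N_t = p$N_t, kappa0 = p$kappa0,
    kappa1 = p$kappa1, gamma_t = p$gamma_t, N0 = p$N0, n = p$n)
}

#' Summarise a model: steady states, stability and bifurcation landmarks
#'
#' @param object an [exhaustion_model()].
#' @param ... unused.
#' @return A list of class `"summary.exhaustion_model"` with the steady-state
#'   table, the transcritical threshold, and f(0).
#' @export
summary.exhaustion_model <- function(object, ...) {
  st <- find_steady_states(object$params)
  structure(list(steady_states = st,
                 lambda_tr = lambda_transcritical(object$params),
                 f0 = f_of_N(0, object$params),
                 params = object$params),
            class = "summary.exhaustion_model")
}

#' @export
print.summary.exhaustion_model <- function(x, ...) {
  print(x$steady_states)
  cat(sprintf("f(0) = %.4g; transcritical threshold lam_tr = %.4g (lam_t %s)\n",
              x$f0, x$lambda_tr,
              if (x$params$lam_t > x$lambda_tr) "above: elimination possible"
              else "below: tumour-free state unstable"))
  invisible(x)
}

#' Simulate an exhaustion model
#'
#' Integrates either the reduced three-variable system or the full
#' exhaustion-compartment system over a horizon given in days (converted to
#' dimensionless time with the model's growth rate).
#'
#' @param object an [exhaustion_model()].
#' @param nsim number of trajectories (kept for generic compatibility; the
#'   model is deterministic so values other than 1 are rejected).
#' @param seed ignored (deterministic model); kept for generic compatibility.
#' @param t_end_days simulation horizon in days. Default 250.
#' @param which `"reduced"` (default) or `"discrete"`.
#' @param ... passed on to [simulate_reduced()] / [simulate_discrete()]
#'   (`n_out`, `solver_opts`, `state0`).
#' @return An `exhaustion_trajectory`.
#' @export
simulate.exhaustion_model <- function(object, nsim = 1, seed = NULL,
                                      t_end_days = 250,
                                      which = c("reduced", "discrete"), ...) {
  if (nsim != 1) stop("the model is deterministic; nsim must be 1",
                      call. = FALSE)
  which <- match.arg(which)
  t_end <- t_end_days * growth_rate(object$params)
  if (which == "reduced")
    simulate_reduced(object$params, t_end, sched = object$schedule, ...)
  else
    simulate_discrete(object$params, t_end, sched = object$schedule, ...)
}

#' @export
plot.exhaustion_model <- function(x, t_end_days = 250, ...) {
  plot(simulate(x, t_end_days = t_end_days), ...)
}
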