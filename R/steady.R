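#' Tumour-nullcline balance function f(N)
#'
#' Nontrivial steady states of the reduced model satisfy 1 - N* = f(N*),
#' where f(N) = lam_t * sigma(N) / (gamma_t + kappa0 + kappa1 N) balances
#' exhaustion-weighted T-cell kill against logistic growth. Its value at the
#' origin, f(0) = lam_t / (gamma_t + kappa0), controls both the parity of the
#' nontrivial root count and the stability of the tumour-free state.
#'
#' @param N tumour burden (vectorised).
#' @param params a [dimensionless_parameters()] object.
#' @return f evaluated at `N`.
#' @export
f_of_N <- function(N, params) {
  params$lam_t * influx_rate(N, params) /
    (params$gamma_t + params$kappa0 + params$kappa1 * N)
}

#' Coefficients of the steady-state quartic
#'
#' Clearing the (strictly positive) denominators of 1 - N = f(N) yields
#' (1 - N)(gamma_t + kappa0 + kappa1 N)(1 + N^2/N_t^2) =
#' lam_t (1 + N^2/N_t^2 + sigma_t N), a degree-4 polynomial whose real roots
#' in (0, 1) are exactly the nontrivial steady states; no spurious roots are
#' introduced.
#'
#' @param params a [dimensionless_parameters()] object.
#' @return Numeric vector of 5 coefficients, constant term first.
#' @export
steady_quartic_coefficients <- function(params) {
  a <- params$gamma_t + params$kappa0
  k1 <- params$kappa1
  cc <- 1 / params$N_t^2
  lam <- params$lam_t
  c(a - lam,
    (k1 - a) - lam * params$sigma_t,
    cc * a - k1 - lam * cc,
    cc * (k1 - a),
    -cc * k1)
}

# real quartic roots in (0,1): companion-matrix roots (polyroot), filtered,
# deduplicated and polished by bisection on 1 - N - f(N)
positive_steady_roots <- function(params) {
  co <- steady_quartic_coefficients(params)
  z <- polyroot(co)
  r <- Re(z[abs(Im(z)) < 1e-9])
  r <- sort(r[r > 1e-12 & r < 1 - 1e-12])
  if (length(r) == 0) return(numeric(0))
  r <- r[c(TRUE, diff(r) > 1e-8)]
  h <- function(N) 1 - N - f_of_N(N, params)
  vapply(r, function(x) {
    lo <- max(x - 1e-6, 1e-13); hi <- min(x + 1e-6, 1 - 1e-13)
    if (h(lo) * h(hi) < 0) stats::uniroot(h, c(lo, hi), tol = 1e-14)$root
    else x                               # near-double root at a fold
  }, numeric(1))
}

#' T-cell total and mean exhaustion at a steady state
#'
#' Given a steady tumour burden N*, the T-cell total is Theta* =
#' sigma(N*) / gamma_t and the mean exhaustion level is mu* =
#' (kappa0 + kappa1 N*) / (gamma_t + kappa0 + kappa1 N*), a strictly
#' increasing function of N*.
#'
#' @param N_star steady tumour burden (vectorised, >= 0).
#' @param params a [dimensionless_parameters()] object.
#' @return A list with components `Theta_star` and `mu_star`.
#' @export
steady_theta_mu <- function(N_star, params) {
  kN <- params$kappa0 + params$kappa1 * N_star
  list(Theta_star = influx_rate(N_star, params) / params$gamma_t,
       mu_star = kN / (params$gamma_t + kN))
}

#' Skew parameter of the steady exhaustion distribution
#'
#' p* = 1 - gamma_t / (kappa0 + kappa1 N*) determines the shape of the steady
#' T-cell distribution across exhaustion levels: positive p* gives a convex
#' increasing (exhaustion-skewed) profile, negative p* a monotonically
#' decreasing (activity-skewed) profile, and p* = 0 (attained at
#' N* = (gamma_t - kappa0)/kappa1) a uniform profile. p* always lies in
#' [1 - gamma_t/kappa0, 1).
#'
#' @inheritParams steady_theta_mu
#' @return p* (vectorised over `N_star`).
#' @export
skew_parameter <- function(N_star, params) {
  1 - params$gamma_t / (params$kappa0 + params$kappa1 * N_star)
}

#' Steady exhaustion distribution at a given tumour burden
#'
#' T0* = sigma(N*) / ((n + 1 - p*)(kappa0 + kappa1 N*)) with the upward
#' recursion T_j* = (n - j + 1) / (n - j + 1 - p*) T_{j-1}*; the denominators
#' stay positive because p* < 1. The distribution's total and first moment
#' reproduce Theta* and mu* from [steady_theta_mu()].
#'
#' @param N_star a single steady tumour burden (>= 0).
#' @param params a [dimensionless_parameters()] object (supplies `n`).
#' @return A list as returned by [distribution_moments()].
#' @export
steady_distribution <- function(N_star, params) {
  stopifnot(length(N_star) == 1L, N_star >= 0)
  n <- params$n
  p <- skew_parameter(N_star, params)
  kN <- params$kappa0 + params$kappa1 * N_star
  T <- numeric(n + 1)
  T[1] <- influx_rate(N_star, params) / ((n + 1 - p) * kN)
  for (j in seq_len(n))
    T[j + 1] <- (n - j + 1) / (n - j + 1 - p) * T[j]
  distribution_moments(stats::setNames(T, paste0("T", 0:n)))
}

# stationary points of the branch parametrisation lam_t(N) at fixed kappa1;
# used to attribute a lone stable root to the equilibrium or escape branch
branch_fold_positions <- function(params, n_grid = 4001) {
  N <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  lam <- (1 - N) * (params$gamma_t + params$kappa0 + params$kappa1 * N) /
    influx_rate(N, params)
  d <- diff(lam)
  idx <- which(d[-1] * d[-length(d)] < 0)
  N[idx + 1]
}

label_steady_states <- function(roots, stable, params) {
  labs <- rep("intermediate", length(roots))
  S <- which(stable)
  if (length(S) >= 2) {
    labs[S] <- "equilibrium"
    labs[S[length(S)]] <- "escape"
  } else if (length(S) == 1) {
    s <- roots[S]
    U <- roots[!stable]
    if (any(U < s)) labs[S] <- "escape"
    else if (any(U > s)) labs[S] <- "equilibrium"
    else {
      z <- branch_fold_positions(params)
      labs[S] <- if (length(z) == 0) {
        if (s > 0.5) "escape" else "equilibrium"
      } else if (s > max(z)) "escape"
      else if (s < min(z)) "equilibrium"
      else if (s >= mean(range(z))) "escape" else "equilibrium"
    }
  }
  labs
}

#' Find all steady states of the reduced model
#'
#' Returns the tumour-free state plus every real root of the steady-state
#' quartic in (0, 1), each with its T-cell total, mean exhaustion, skew
#' parameter, eigenvalues, linear stability, and an immunoediting outcome
#' label. The tumour-free state is `"elimination"`; positive stable roots are
#' labelled `"equilibrium"` (lower branch) or `"escape"` (upper branch), and
#' unstable interior roots `"intermediate"`. A lone stable positive root is
#' attributed to a branch via the unstable roots flanking it or, failing
#' that, via the fold structure of the kill-rate branch parametrisation.
#'
#' @param params a [dimensionless_parameters()] object.
#' @return A data frame of class `"steady_states"` with one row per state and
#'   columns `N_star, Theta_star, mu_star, p_star, eig1, eig2, eig3` (complex),
#'   `stable`, `outcome`.
#' @export
find_steady_states <- function(params) {
  validate_dimensionless(params)
  roots <- positive_steady_roots(params)
  g <- g_of_N(roots, params)
  stable_pos <- g < 0
  labs <- label_steady_states(roots, stable_pos, params)
  all_N <- c(0, roots)
  th <- steady_theta_mu(all_N, params)
  eig <- lapply(all_N, function(N)
    if (N == 0) trivial_eigenvalues(params)$alphas
    else nontrivial_eigenvalues(N, params)$alphas)
  eig <- do.call(rbind, eig)
  out <- data.frame(
    N_star = all_N,
    Theta_star = th$Theta_star,
    mu_star = th$mu_star,
    p_star = skew_parameter(all_N, params),
    stable = c(params$lam_t > params$gamma_t + params$kappa0, stable_pos),
    outcome = c("elimination", labs),
    stringsAsFactors = FALSE)
  out$eig1 <- eig[, 1]; out$eig2 <- eig[, 2]; out$eig3 <- eig[, 3]
  structure(out, class = c("steady_states", "data.frame"), params = params)
}

#' @export
print.steady_states <- function(x, ...) {
  cat("Steady states of the reduced tumour-immune model\n")
  df <- as.data.frame(x)
  df$eig1 <- signif(df$eig1, 4); df$eig2 <- signif(df$eig2, 4)
  df$eig3 <- signif(df$eig3, 4)
  print.data.frame(df, digits = 5, row.names = FALSE)
  invisible(x)
}
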