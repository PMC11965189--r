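#' Eigenvalues at the tumour-free steady state
#'
#' The linearisation about (Theta, mu, N) = (1/gamma_t, kappa0/(kappa0 +
#' gamma_t), 0) has eigenvalues -gamma_t, -(gamma_t + kappa0) and 1 - f(0).
#' The state is therefore stable exactly when lam_t exceeds the transcritical
#' threshold gamma_t + kappa0.
#'
#' @param params a [dimensionless_parameters()] object.
#' @return A list with `alphas` (three eigenvalues, as complex) and `stable`.
#' @export
trivial_eigenvalues <- function(params) {
  a <- c(-params$gamma_t,
         -(params$gamma_t + params$kappa0),
         1 - f_of_N(0, params))
  list(alphas = as.complex(a), stable = all(Re(a) < 0))
}

#' Stability indicator g(N*) for nontrivial steady states
#'
#' g(N*) = -gamma_t - k(N*) + (1 - N*) k'(N*) - lam_t * sigma'(N*), with
#' k(N) = kappa0 + kappa1 N and sigma(N) the influx rate. A nontrivial steady
#' state is linearly stable iff g(N*) < 0; folds along a branch occur where
#' g(N*) = 0.
#'
#' @param N_star steady tumour burden (vectorised).
#' @param params a [dimensionless_parameters()] object.
#' @return g evaluated at `N_star`.
#' @export
g_of_N <- function(N_star, params) {
  -params$gamma_t - exhaustion_rate(N_star, params) +
    (1 - N_star) * params$kappa1 -
    params$lam_t * influx_rate_deriv(N_star, params)
}

#' Eigenvalues at a nontrivial steady state
#'
#' One eigenvalue is always -gamma_t; the remaining two solve
#' alpha^2 + (gamma_t + k(N*) + N*) alpha - N* g(N*) = 0. Since the linear
#' coefficient is positive, the state is stable iff g(N*) < 0; a complex pair
#' signals damped oscillations onto the equilibrium.
#'
#' @param N_star a single positive steady tumour burden (must solve the
#'   steady-state equation to ~1e-8, else an error is raised).
#' @param params a [dimensionless_parameters()] object.
#' @return A list with `alphas` (complex, length 3: -gamma_t first) and
#'   `stable`.
#' @export
nontrivial_eigenvalues <- function(N_star, params) {
  stopifnot(length(N_star) == 1L, N_star > 0)
  if (abs(1 - N_star - f_of_N(N_star, params)) > 1e-8)
    stop("N_star does not satisfy the steady-state condition", call. = FALSE)
  b <- params$gamma_t + exhaustion_rate(N_star, params) + N_star
  cc <- -N_star * g_of_N(N_star, params)
  disc <- as.complex(b^2 - 4 * cc)
  quad <- c((-b + sqrt(disc)) / 2, (-b - sqrt(disc)) / 2)
  alphas <- c(as.complex(-params$gamma_t), quad)
  list(alphas = alphas, stable = all(Re(alphas) < 0))
}

#' Transcritical bifurcation threshold in the kill rate
#'
#' Tumour elimination requires lam_t > gamma_t + kappa0; at equality the
#' tumour-free state exchanges stability with the equilibrium branch.
#'
#' @param params a [dimensionless_parameters()] object.
#' @return The threshold value gamma_t + kappa0.
#' @export
lambda_transcritical <- function(params) params$gamma_t + params$kappa0

# refine a sign change of `fun` between grid neighbours by bisection
refine_sign_change <- function(fun, lo, hi, tol = 1e-10) {
  flo <- fun(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- fun(mid)
    if (sign(fm) == sign(flo)) lo <- mid else hi <- mid
    if (sign(fm) == sign(flo)) flo <- fm
  }
  (lo + hi) / 2
}

branch_generic <- function(params, N_grid, param_of_N, param_name) {
  stopifnot(all(N_grid > 0 & N_grid < 1))
  N_grid <- sort(N_grid)
  val <- param_of_N(N_grid)
  pts <- data.frame(param = val, N_star = N_grid)
  # stability along the branch: g evaluated with the branch's own parameter
  gvals <- vapply(seq_along(N_grid), function(i) {
    q <- params; q[[param_name]] <- val[i]
    g_of_N(N_grid[i], q)
  }, numeric(1))
  pts$stable <- gvals < 0
  th <- steady_theta_mu(N_grid, params)  # Theta*, mu* depend on kappa1 too
  if (param_name == "kappa1") {
    th <- lapply(seq_along(N_grid), function(i) {
      q <- params; q$kappa1 <- val[i]
      steady_theta_mu(N_grid[i], q)
    })
    pts$Theta_star <- vapply(th, `[[`, numeric(1), "Theta_star")
    pts$mu_star <- vapply(th, `[[`, numeric(1), "mu_star")
  } else {
    pts$Theta_star <- th$Theta_star
    pts$mu_star <- th$mu_star
  }
  # folds: sign changes of the derivative of param(N) along the branch
  d <- diff(val)
  idx <- which(d[-1] * d[-length(d)] < 0)
  folds <- vapply(idx, function(i) {
    dfun <- function(N) {
      h <- 1e-7
      (param_of_N(min(N + h, 1 - 1e-12)) - param_of_N(max(N - h, 1e-12))) /
        (min(N + h, 1 - 1e-12) - max(N - h, 1e-12))
    }
    refine_sign_change(dfun, N_grid[i], N_grid[i + 2])
  }, numeric(1))
  fold_df <- data.frame(N_star = folds, param = param_of_N(folds))
  structure(list(parameter = param_name, points = pts, folds = fold_df,
                 transcritical = if (param_name == "lam_t")
                   lambda_transcritical(params) else NULL,
                 params = params),
            class = "bifurcation_branch")
}

#' One-parameter steady-state branch in the kill rate
#'
#' The nontrivial branch is single-valued in N*, so rather than numerical
#' continuation the branch is parameterised explicitly by N*:
#' lam_t(N*) = (1 - N*)(gamma_t + kappa0 + kappa1 N*) / sigma(N*). Stability
#' follows from the sign of g along the branch, folds are located where
#' d lam_t / d N* changes sign (refined by bisection to |dN*| < 1e-10), and
#' the branch meets the trivial state at lam_t -> gamma_t + kappa0 as
#' N* -> 0 (the transcritical point).
#'
#' @param params a [dimensionless_parameters()] object (its `lam_t` is
#'   ignored along the branch).
#' @param N_grid grid of steady tumour burdens in (0, 1); default 4001
#'   equally spaced points.
#' @return A `bifurcation_branch` object: a list with `points` (param, N*,
#'   stability, Theta*, mu*), `folds`, and `transcritical`.
#' @export
branch_in_lambda <- function(params, N_grid = NULL) {
  if (is.null(N_grid)) N_grid <- seq(1e-6, 1 - 1e-6, length.out = 4001)
  lam_of <- function(N)
    (1 - N) * (params$gamma_t + params$kappa0 + params$kappa1 * N) /
      influx_rate(N, params)
  branch_generic(params, N_grid, lam_of, "lam_t")
}

#' One-parameter steady-state branch in the exhaustion rate
#'
#' As [branch_in_lambda()], using the explicit parametrisation
#' kappa1(N*) = (lam_t sigma(N*) / (1 - N*) - gamma_t - kappa0) / N*.
#' Portions where kappa1(N*) <= 0 (possible for lam_t below the transcritical
#' threshold at small N*) are dropped as unphysical.
#'
#' @param params a [dimensionless_parameters()] object (its `kappa1` is
#'   ignored along the branch).
#' @inheritParams branch_in_lambda
#' @return A `bifurcation_branch` object.
#' @export
branch_in_kappa1 <- function(params, N_grid = NULL) {
  if (is.null(N_grid)) N_grid <- seq(1e-6, 1 - 1e-6, length.out = 4001)
  k1_of <- function(N)
    (params$lam_t * influx_rate(N, params) / (1 - N) -
       params$gamma_t - params$kappa0) / N
  br <- branch_generic(params, N_grid, k1_of, "kappa1")
  keep <- br$points$param > 0
  br$points <- br$points[keep, , drop = FALSE]
  br$folds <- br$folds[br$folds$param > 0, , drop = FALSE]
  br
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat(sprintf("Steady-state branch in %s: %d points, %d fold(s)\n",
              x$parameter, nrow(x$points), nrow(x$folds)))
  if (nrow(x$folds)) {
    cat("  folds at:\n")
    print.data.frame(signif(x$folds, 6), row.names = FALSE)
  }
  if (!is.null(x$transcritical))
    cat(sprintf("  transcritical at %s = %.6g\n", x$parameter,
                x$transcritical))
  invisible(x)
}

#' @export
plot.bifurcation_branch <- function(x, ...) {
  p <- x$points
  graphics::plot(p$param, p$N_star, type = "n", log = "x",
                 xlab = x$parameter, ylab = "N*", ...)
  graphics::points(p$param[p$stable], p$N_star[p$stable], pch = 16, cex = 0.3)
  graphics::points(p$param[!p$stable], p$N_star[!p$stable], pch = 1,
                   cex = 0.3, col = "grey50")
  if (nrow(x$folds))
    graphics::points(x$folds$param, x$folds$N_star, pch = 4, col = "red3")
  invisible(x)
}

# classification of a single (lam_t, kappa1) cell, reusing precomputed branch
# fold positions (which depend only on kappa1 for fixed influx parameters)
classify_parameter_point <- function(params, fold_positions = NULL) {
  roots <- positive_steady_roots(params)
  g <- g_of_N(roots, params)
  stable <- g < 0
  labs <- if (is.null(fold_positions)) {
    label_steady_states(roots, stable, params)
  } else {
    label_with_folds(roots, stable, fold_positions)
  }
  triv <- params$lam_t > lambda_transcritical(params)
  stable_set <- sort(unique(c(if (triv) "elimination", labs[stable])))
  list(total = 1L + length(roots),
       n_stable = as.integer(triv) + sum(stable),
       stable_outcomes = stable_set,
       class_key = paste(1L + length(roots), as.integer(triv) + sum(stable),
                         paste(stable_set, collapse = "+"), sep = "|"))
}

label_with_folds <- function(roots, stable, z) {
  labs <- rep("intermediate", length(roots))
  S <- which(stable)
  if (length(S) >= 2) {
    labs[S] <- "equilibrium"; labs[S[length(S)]] <- "escape"
  } else if (length(S) == 1) {
    s <- roots[S]; U <- roots[!stable]
    labs[S] <- if (any(U < s)) "escape"
    else if (any(U > s)) "equilibrium"
    else if (length(z) == 0) { if (s > 0.5) "escape" else "equilibrium" }
    else if (s > max(z)) "escape"
    else if (s < min(z)) "equilibrium"
    else if (s >= mean(range(z))) "escape" else "equilibrium"
  }
  labs
}

#' Two-parameter region map over kill and exhaustion rates
#'
#' Classifies a log-spaced grid in (lam_t, kappa1): each cell records the
#' total number of physically realistic steady states, how many are stable,
#' and the set of stable outcome labels. Cells sharing that triple form a
#' qualitative region; with the default influx parameters the map partitions
#' into five regions (elimination only; bistable elimination/escape;
#' equilibrium only; bistable equilibrium/escape; escape only).
#'
#' @param params a [dimensionless_parameters()] object supplying the fixed
#'   parameters (`lam_t`, `kappa1` are swept).
#' @param lambda_range range of the kill rate; default `c(1e-3, 1)`.
#' @param kappa1_range range of the exhaustion rate; default `c(1e-2, 1e3)`.
#' @param resolution grid points per axis (default 200).
#' @return A `region_map` object: a list with `grid` (a data frame with one
#'   row per cell: lam_t, kappa1, total, n_stable, stable_outcomes,
#'   class_key) and `classes` (the distinct class keys).
#' @export
region_map <- function(params, lambda_range = c(1e-3, 1),
                       kappa1_range = c(1e-2, 1e3), resolution = 200) {
  lam_grid <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                      length.out = resolution))
  k1_grid <- exp(seq(log(kappa1_range[1]), log(kappa1_range[2]),
                     length.out = resolution))
  rows <- vector("list", resolution^2)
  i <- 0L
  for (k1 in k1_grid) {
    q <- params; q$kappa1 <- k1
    z <- branch_fold_positions(q)
    for (lam in lam_grid) {
      q$lam_t <- lam
      cl <- classify_parameter_point(q, z)
      i <- i + 1L
      rows[[i]] <- data.frame(
        lam_t = lam, kappa1 = k1, total = cl$total, n_stable = cl$n_stable,
        stable_outcomes = paste(cl$stable_outcomes, collapse = "+"),
        class_key = cl$class_key, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  structure(list(grid = grid, classes = sort(unique(grid$class_key)),
                 params = params),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("Region map: %d cells, %d distinct qualitative classes\n",
              nrow(x$grid), length(x$classes)))
  tab <- table(x$grid$class_key)
  for (k in names(tab))
    cat(sprintf("  %-40s %6d cells\n", k, tab[[k]]))
  invisible(x)
}

#' Search for tristability along an influx-parameter trajectory
#'
#' For each supplied (sigma_t, N_t) pair, sweeps the kill rate over a dense
#' log grid, recording the maximum number of coexisting physically realistic
#' steady states and the kill-rate interval (if any) on which three outcomes
#' (elimination, equilibrium, escape) are simultaneously stable.
#'
#' @param params a [dimensionless_parameters()] object supplying the fixed
#'   parameters.
#' @param pairs a two-column matrix or data frame of (sigma_t, N_t) values.
#' @param lambda_range kill-rate sweep range; default `c(1e-3, 1)`.
#' @param n_sweep sweep resolution (default 10000).
#' @return A data frame with one row per pair: `sigma_t, N_t, max_states,
#'   tristable` (logical), `lam_lo, lam_hi` (the tristable window, NA when
#'   absent).
#' @export
tristability_window <- function(params, pairs, lambda_range = c(1e-3, 1),
                                n_sweep = 10000) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("sigma_t", "N_t")
  lam_grid <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                      length.out = n_sweep))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    q <- params
    q$sigma_t <- pairs$sigma_t[i]; q$N_t <- pairs$N_t[i]
    # the state count only changes at folds and the transcritical point, so
    # augment the sweep with midpoints between consecutive breakpoints: a
    # tristable window narrower than the grid spacing is still detected
    br <- branch_in_lambda(q)
    bp <- sort(unique(c(br$folds$param, lambda_transcritical(q))))
    bp <- bp[bp > lambda_range[1] & bp < lambda_range[2]]
    mids <- if (length(bp) > 1) sqrt(bp[-1] * bp[-length(bp)]) else numeric(0)
    lam_all <- sort(unique(c(lam_grid, mids)))
    max_states <- 0L
    tri <- logical(length(lam_all))
    for (j in seq_along(lam_all)) {
      q$lam_t <- lam_all[j]
      roots <- positive_steady_roots(q)
      max_states <- max(max_states, 1L + length(roots))
      tri[j] <- q$lam_t > lambda_transcritical(q) &&
        sum(g_of_N(roots, q) < 0) >= 2
    }
    data.frame(sigma_t = q$sigma_t, N_t = q$N_t, max_states = max_states,
               tristable = any(tri),
               lam_lo = if (any(tri)) min(lam_all[tri]) else NA_real_,
               lam_hi = if (any(tri)) max(lam_all[tri]) else NA_real_)
  })
  do.call(rbind, out)
}
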